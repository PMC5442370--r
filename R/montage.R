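# Montage handling: electrode positions on a spherical head model and the
# grouping of raw electrodes onto the 32 evenly spread extended 10-20
# locations.  The shipped montage is synthetic: 32 standard centre
# positions derived from 10-20 arc geometry plus raw electrodes placed on
# a Fibonacci spiral over the scalp cap.  It is a stand-in for a vendor
# cap layout and is replaceable via the `centres` argument.

sphToXyz <- function(incDeg, aziDeg, radius) {
  inc <- incDeg * pi / 180
  azi <- aziDeg * pi / 180
  cbind(x = radius * sin(inc) * sin(azi),
        y = radius * sin(inc) * cos(azi),
        z = radius * cos(inc))
}

# great-circle (arc) distance in cm between rows of two xyz matrices
arcDist <- function(a, b, radius) {
  d <- tcrossprod(a, b) / radius^2
  d[d > 1] <- 1
  d[d < -1] <- -1
  radius * acos(d)
}

#' Build the synthetic spherical montage
#'
#' Places \code{nElectrodes} raw electrodes quasi-uniformly (Fibonacci
#' spiral) on the scalp cap of a spherical head and groups them onto the
#' 32 extended 10-20 centre locations: every electrode within
#' \code{groupRadius} cm (arc length) of a centre is a member of that
#' centre's group.  Groups may overlap; a centre with no electrode inside
#' the radius adopts its nearest electrode.
#'
#' @param nElectrodes raw electrode count (default 128)
#' @param headRadius head sphere radius in cm (default 9.5)
#' @param groupRadius grouping radius in cm along the scalp (default 3)
#' @param capLimit maximal inclination of raw electrodes, degrees
#' @param centres data.frame(name, inclination_deg, azimuth_deg); default is
#'   the shipped synthetic extended 10-20 table
#' @return list with elements \code{electrodes} (data.frame name,x,y,z),
#'   \code{centres} (data.frame name,x,y,z), \code{membership} (named list of
#'   electrode indices per centre), \code{groupRadius}, \code{headRadius}
#' @export
makeSyntheticMontage <- function(nElectrodes = 128L, headRadius = 9.5,
                                 groupRadius = 3, capLimit = 105,
                                 centres = NULL) {
  if (is.null(centres)) {
    path <- system.file("extdata", "synthetic_montage_centres.csv",
                        package = "somnidec")
    centres <- read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(centres) >= 1L)
  cXyz <- sphToXyz(centres$inclination_deg, centres$azimuth_deg, headRadius)
  # Fibonacci spiral over the cap inclination range [0, capLimit]
  i <- seq_len(nElectrodes)
  zFrac <- 1 - (i - 0.5) / nElectrodes * (1 - cos(capLimit * pi / 180))
  inc <- acos(zFrac) * 180 / pi
  azi <- (i * 137.50776405003785) %% 360
  eXyz <- sphToXyz(inc, azi, headRadius)
  rownames(eXyz) <- paste0("E", i)
  dists <- arcDist(cXyz, eXyz, headRadius)  # centres x electrodes
  membership <- lapply(seq_len(nrow(centres)), function(g) {
    m <- which(dists[g, ] <= groupRadius)
    if (!length(m)) m <- which.min(dists[g, ])
    unname(m)
  })
  names(membership) <- centres$name
  list(electrodes = data.frame(name = rownames(eXyz), eXyz,
                               row.names = NULL),
       centres = data.frame(name = centres$name, cXyz, row.names = NULL),
       membership = membership,
       groupRadius = groupRadius, headRadius = headRadius)
}

# arc distances between raw electrodes of a montage
electrodeDistances <- function(montage) {
  e <- as.matrix(montage$electrodes[, c("x", "y", "z")])
  arcDist(e, e, montage$headRadius)
}
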