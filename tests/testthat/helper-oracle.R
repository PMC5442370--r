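# Independent brute-force oracle for the two-step classifier on tiny
# problems: the linear SVM is solved by iterated grid refinement on the
# primal objective (margin maximization with an unregularized bias), and
# the two-step procedure is reproduced with explicit loops.  Nothing in
# here calls the package's decoding path.

oracleSvmFit <- function(X, y, C = 1, gridN = 9) {
  p <- ncol(X)
  obj <- function(wb) {
    w <- wb[seq_len(p)]
    b <- wb[p + 1]
    0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (as.numeric(X %*% w) + b)))
  }
  best <- rep(0, p + 1)
  bestVal <- obj(best)
  width <- 8
  while (width > 1e-5) {
    repeat {
      improved <- FALSE
      # coordinate-wise grid sweeps at the current scale
      for (d in seq_len(p + 1)) {
        grid <- best[d] + seq(-width, width, length.out = gridN)
        for (g in grid) {
          cand <- best
          cand[d] <- g
          v <- obj(cand)
          if (v < bestVal - 1e-12) {
            bestVal <- v
            best <- cand
            improved <- TRUE
          }
        }
      }
      # pairwise diagonal moves escape axis-aligned stalls of the
      # piecewise-linear hinge surface
      for (d1 in seq_len(p)) for (d2 in (d1 + 1):(p + 1)) {
        for (s1 in c(-width, width)) for (s2 in c(-width, width)) {
          cand <- best
          cand[d1] <- cand[d1] + s1
          cand[d2] <- cand[d2] + s2
          v <- obj(cand)
          if (v < bestVal - 1e-12) {
            bestVal <- v
            best <- cand
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    width <- width * 0.5
  }
  # polish the grid minimum with derivative-free simplex restarts (the
  # hinge surface is convex, so this only tightens the same optimum)
  for (i in 1:4) {
    nm <- optim(best, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    if (nm$value < bestVal) {
      best <- nm$par
      bestVal <- nm$value
    }
  }
  list(w = best[seq_len(p)], b = best[p + 1], value = bestVal)
}

# explicit-loop two-step procedure on a feature array (nights x channels
# x bins): inner LOSO channel weights, weighted average, main SVM, and
# evaluation on the held-out fold
oracleTwoStep <- function(feat, y, subjIdx, foldOf, C = 1) {
  folds <- sort(unique(foldOf))
  nCh <- dim(feat)[2]
  nB <- dim(feat)[3]
  correct <- 0
  total <- 0
  for (f in folds) {
    testSubj <- which(foldOf == f)
    trN <- which(!(subjIdx %in% testSubj))
    teN <- which(subjIdx %in% testSubj)
    trSub <- unique(subjIdx[trN])
    wch <- numeric(nCh)
    for (ch in seq_len(nCh)) {
      corr <- 0
      tot <- 0
      for (s in trSub) {
        inn <- trN[subjIdx[trN] != s]
        out <- trN[subjIdx[trN] == s]
        fit <- oracleSvmFit(matrix(feat[inn, ch, ], length(inn), nB),
                            y[inn], C)
        dec <- as.numeric(matrix(feat[out, ch, ], length(out), nB) %*%
                            fit$w) + fit$b
        corr <- corr + sum((dec >= 0) == (y[out] > 0))
        tot <- tot + length(out)
      }
      wch[ch] <- corr / tot
    }
    wavg <- function(idx) {
      out <- matrix(0, length(idx), nB)
      for (ch in seq_len(nCh)) out <- out + wch[ch] * feat[idx, ch, ]
      out / sum(wch)
    }
    fit <- oracleSvmFit(wavg(trN), y[trN], C)
    dec <- as.numeric(wavg(teN) %*% fit$w) + fit$b
    correct <- correct + sum((dec >= 0) == (y[teN] > 0))
    total <- total + length(teN)
  }
  list(accuracy = correct / total, channelWeights = wch)
}
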