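#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// C-SVC with linear kernel, solved by SMO on the standard dual
//   min 0.5 a' Q a - 1'a,  0 <= a_i <= C,  sum_i y_i a_i = 0,
// with Q_ij = y_i y_j x_i.x_j and an unregularized bias recovered from
// the KKT conditions (the formulation of libsvm, which the original
// analysis used).  Working pairs are chosen by the maximal-violating-
// pair rule, which is deterministic: identical inputs give identical
// solutions and negating y negates (w, b).

struct SvmModel {
    std::vector<double> w;
    double b;
};

static SvmModel fit_smo(const double* X, int n, int p, const double* y,
                        double C, int max_iter, double eps) {
    std::vector<double> alpha(n, 0.0), w(p, 0.0), dec(n, 0.0);
    std::vector<double> xsq(n);
    for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < p; ++j) {
            double v = X[i + (size_t)n * j];
            s += v * v;
        }
        xsq[i] = s;
    }
    for (int it = 0; it < max_iter; ++it) {
        // F_i = -y_i * grad_i = y_i - y_i^2 * (w.x_i) ... with
        // grad_i = y_i*(w.x_i) - 1, so F_i = y_i*(1 - y_i*(w.x_i)) ...
        // simplifies to F_i = y_i - dec_i with dec_i = w.x_i.
        int iu = -1, il = -1;
        double m = -1e300, M = 1e300;
        for (int t = 0; t < n; ++t) {
            double F = y[t] - dec[t];
            bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
            bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
            if (up && F > m) { m = F; iu = t; }
            if (lo && F < M) { M = F; il = t; }
        }
        if (iu < 0 || il < 0 || m - M < eps) break;
        int i = iu, j = il;
        double kij = 0.0;
        for (int q = 0; q < p; ++q)
            kij += X[i + (size_t)n * q] * X[j + (size_t)n * q];
        double eta = xsq[i] + xsq[j] - 2.0 * kij;
        if (eta < 1e-12) eta = 1e-12;
        double t_step = (m - M) / eta;
        // alpha_i += y_i * t, alpha_j -= y_j * t, subject to the box
        double lo_t, hi_t;
        if (y[i] > 0) { lo_t = -alpha[i]; hi_t = C - alpha[i]; }
        else          { lo_t = alpha[i] - C; hi_t = alpha[i]; }
        double lo2, hi2;
        if (y[j] > 0) { lo2 = alpha[j] - C; hi2 = alpha[j]; }
        else          { lo2 = -alpha[j]; hi2 = C - alpha[j]; }
        if (lo2 > lo_t) lo_t = lo2;
        if (hi2 < hi_t) hi_t = hi2;
        if (t_step > hi_t) t_step = hi_t;
        if (t_step < lo_t) t_step = lo_t;
        if (t_step == 0.0) break;
        alpha[i] += y[i] * t_step;
        alpha[j] -= y[j] * t_step;
        for (int q = 0; q < p; ++q) {
            double d = t_step * (X[i + (size_t)n * q] - X[j + (size_t)n * q]);
            w[q] += d;
        }
        for (int t = 0; t < n; ++t) {
            double d = 0.0;
            for (int q = 0; q < p; ++q)
                d += w[q] * X[t + (size_t)n * q];
            dec[t] = d;
        }
    }
    // bias from the KKT conditions: free SVs pin it exactly; otherwise
    // take the midpoint of the feasible interval
    double bsum = 0.0;
    int nfree = 0;
    double blo = -1e300, bhi = 1e300;
    for (int t = 0; t < n; ++t) {
        double F = y[t] - dec[t];
        if (alpha[t] > 1e-10 && alpha[t] < C - 1e-10) {
            bsum += F;
            ++nfree;
        } else {
            bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
            bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
            if (up && F > blo) blo = F;
            if (lo && F < bhi) bhi = F;
        }
    }
    SvmModel model;
    model.w = w;
    if (nfree > 0) model.b = bsum / nfree;
    else if (blo > -1e300 && bhi < 1e300) model.b = 0.5 * (blo + bhi);
    else if (bhi < 1e300) model.b = bhi;
    else if (blo > -1e300) model.b = blo;
    else model.b = 0.0;
    return model;
}

// [[Rcpp::export(name = ".cppSvmFit")]]
List cppSvmFit(NumericMatrix X, NumericVector y, double C = 1.0,
               int maxIter = 20000, double tol = 1e-6) {
    int n = X.nrow(), p = X.ncol();
    SvmModel m = fit_smo(REAL(X), n, p, REAL(y), C, maxIter, tol);
    return List::create(_["w"] = NumericVector(m.w.begin(), m.w.end()),
                        _["b"] = m.b);
}

// Leave-one-subject-out accuracy and mean |weight| profile for every
// channel of a (nights x channels x bins) feature array.  Both nights
// of a subject are always held out together.  Decision-value ties
// (exactly zero) are assigned to the positive class.
//
// feat: numeric array, dim = c(nNights, nChannels, nBins)
// subj: 0-based subject index per night
// y:    +1 / -1 labels per night
// [[Rcpp::export(name = ".cppLosoChannels")]]
List cppLosoChannels(NumericVector feat, IntegerVector dims,
                     IntegerVector subj, NumericVector y, double C = 1.0,
                     int maxIter = 20000, double tol = 1e-6) {
    int nN = dims[0], nC = dims[1], nB = dims[2];
    int nSub = 0;
    for (int i = 0; i < nN; ++i) if (subj[i] + 1 > nSub) nSub = subj[i] + 1;
    NumericVector acc(nC);
    NumericMatrix mabsw(nC, nB);
    std::vector<double> Xtr;
    std::vector<double> ytr;
    for (int c = 0; c < nC; ++c) {
        int correct = 0, total = 0, nfits = 0;
        for (int s = 0; s < nSub; ++s) {
            int ntr = 0;
            for (int i = 0; i < nN; ++i) if (subj[i] != s) ++ntr;
            if (ntr == 0 || ntr == nN) continue; // subject absent or alone
            Xtr.assign((size_t)ntr * nB, 0.0);
            ytr.assign(ntr, 0.0);
            int r = 0;
            for (int i = 0; i < nN; ++i) {
                if (subj[i] == s) continue;
                for (int jb = 0; jb < nB; ++jb)
                    Xtr[r + (size_t)ntr * jb] =
                        feat[i + (size_t)nN * (c + (size_t)nC * jb)];
                ytr[r] = y[i];
                ++r;
            }
            SvmModel m = fit_smo(Xtr.data(), ntr, nB, ytr.data(), C,
                                 maxIter, tol);
            for (int i = 0; i < nN; ++i) {
                if (subj[i] != s) continue;
                double dec = m.b;
                for (int jb = 0; jb < nB; ++jb)
                    dec += m.w[jb] * feat[i + (size_t)nN * (c + (size_t)nC * jb)];
                int pred = dec >= 0 ? 1 : -1;
                if ((pred > 0) == (y[i] > 0)) ++correct;
                ++total;
            }
            for (int jb = 0; jb < nB; ++jb) mabsw(c, jb) += std::fabs(m.w[jb]);
            ++nfits;
        }
        acc[c] = total > 0 ? (double)correct / total : NA_REAL;
        if (nfits > 0)
            for (int jb = 0; jb < nB; ++jb) mabsw(c, jb) /= nfits;
    }
    return List::create(_["accuracy"] = acc, _["meanAbsW"] = mabsw);
}
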