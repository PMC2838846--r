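// Profile-HMM log-odds scoring in log2 space.
//
// Model layout passed from R (all log2 odds / log2 probabilities):
//   lM : L x A      match emission log-odds, column A is the wildcard X (all 0)
//   lI : (L+1) x A  insert emission log-odds for I_0..I_L (I_L is never reached)
//   lt : (L+1) x 7  transitions out of node r (row r, 0-based), columns
//        0 MM  M_r -> M_{r+1}   (r = 0: Begin -> M_1; r = L: M_L -> End)
//        1 MI  M_r -> I_r
//        2 MD  M_r -> D_{r+1}
//        3 IM  I_r -> M_{r+1}
//        4 II  I_r -> I_r
//        5 DM  D_r -> M_{r+1}   (r = L: D_L -> End)
//        6 DD  D_r -> D_{r+1}
//   idx : 1-based residue column indices into the emission matrices.
//
// Glocal mode: the path runs Begin -> ... -> End and must emit every residue.
// Local mode: a fragment M_i..M_j is aligned with uniform fragment probability
// 2 / (L (L + 1)); residues outside the fragment are scored by the null model
// and therefore contribute zero bits.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double lse2(double a, double b) {
    if (a == R_NegInf) return b;
    if (b == R_NegInf) return a;
    double m = a > b ? a : b;
    double d = a > b ? b - a : a - b; // <= 0
    return m + std::log1p(std::exp(d * M_LN2)) / M_LN2;
}

static inline double max3(double a, double b, double c) {
    return std::max(a, std::max(b, c));
}

// [[Rcpp::export(name = ".cpp_phmm_score")]]
double cpp_phmm_score(const NumericMatrix& lM, const NumericMatrix& lI,
                      const NumericMatrix& lt, const IntegerVector& idx,
                      bool local, bool forward) {
    const int L = lM.nrow();
    const int n = idx.size();
    if (n < 1) stop("sequence must contain at least one residue");

    std::vector<double> pM(L + 1, R_NegInf), pI(L + 1, R_NegInf), pD(L + 1, R_NegInf);
    std::vector<double> cM(L + 1, R_NegInf), cI(L + 1, R_NegInf), cD(L + 1, R_NegInf);

    double best = R_NegInf; // local-mode accumulator
    const double entry = local ? std::log2(2.0 / (double(L) * double(L + 1))) : R_NegInf;

    if (!local) {
        // position 0: Begin and delete chain
        pM[0] = 0.0;
        for (int k = 1; k <= L; ++k) {
            double fromM = pM[k - 1] + lt(k - 1, 2);
            double fromD = (k >= 2) ? pD[k - 1] + lt(k - 1, 6) : R_NegInf;
            pD[k] = forward ? lse2(fromM, fromD) : std::max(fromM, fromD);
        }
    }

    for (int p = 0; p < n; ++p) {
        const int a = idx[p] - 1;
        // match states
        cM[0] = R_NegInf;
        for (int k = 1; k <= L; ++k) {
            double fm = pM[k - 1] + lt(k - 1, 0);
            double fi = pI[k - 1] + lt(k - 1, 3);
            double fd = pD[k - 1] + lt(k - 1, 5);
            double v;
            if (forward) {
                v = lse2(lse2(fm, fi), fd);
                if (local) v = lse2(v, entry);
            } else {
                v = max3(fm, fi, fd);
                if (local) v = std::max(v, entry);
            }
            cM[k] = lM(k - 1, a) + v;
            if (local) best = forward ? lse2(best, cM[k]) : std::max(best, cM[k]);
        }
        // insert states I_0 .. I_{L-1}
        for (int k = 0; k < L; ++k) {
            if (local && k == 0) { cI[k] = R_NegInf; continue; }
            double fm = pM[k] + lt(k, 1);
            double fi = pI[k] + lt(k, 4);
            cI[k] = lI(k, a) + (forward ? lse2(fm, fi) : std::max(fm, fi));
        }
        cI[L] = R_NegInf;
        // delete states (same position, after matches)
        cD[0] = R_NegInf;
        for (int k = 1; k <= L; ++k) {
            double fm = cM[k - 1] + lt(k - 1, 2);
            double fd = cD[k - 1] + lt(k - 1, 6);
            cD[k] = forward ? lse2(fm, fd) : std::max(fm, fd);
        }
        std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
    }

    if (local) return best;
    double endM = pM[L] + lt(L, 0);
    double endD = pD[L] + lt(L, 5);
    return forward ? lse2(endM, endD) : std::max(endM, endD);
}

// Local Viterbi with fragment coordinates: returns (score, start, end),
// 1-based inclusive positions of the residues emitted by the best fragment.
// [[Rcpp::export(name = ".cpp_phmm_local_hit")]]
NumericVector cpp_phmm_local_hit(const NumericMatrix& lM, const NumericMatrix& lI,
                                 const NumericMatrix& lt, const IntegerVector& idx) {
    const int L = lM.nrow();
    const int n = idx.size();
    if (n < 1) stop("sequence must contain at least one residue");

    std::vector<double> pM(L + 1, R_NegInf), pI(L + 1, R_NegInf), pD(L + 1, R_NegInf);
    std::vector<double> cM(L + 1, R_NegInf), cI(L + 1, R_NegInf), cD(L + 1, R_NegInf);
    std::vector<int> psM(L + 1, 0), psI(L + 1, 0), psD(L + 1, 0);
    std::vector<int> csM(L + 1, 0), csI(L + 1, 0), csD(L + 1, 0);

    const double entry = std::log2(2.0 / (double(L) * double(L + 1)));
    double best = R_NegInf;
    int bestStart = NA_INTEGER, bestEnd = NA_INTEGER;

    for (int p = 0; p < n; ++p) {
        const int a = idx[p] - 1;
        cM[0] = R_NegInf; csM[0] = 0;
        for (int k = 1; k <= L; ++k) {
            double fm = pM[k - 1] + lt(k - 1, 0);
            double fi = pI[k - 1] + lt(k - 1, 3);
            double fd = pD[k - 1] + lt(k - 1, 5);
            double v = entry; int s = p + 1; // start a new fragment here
            if (fm > v) { v = fm; s = psM[k - 1]; }
            if (fi > v) { v = fi; s = psI[k - 1]; }
            if (fd > v) { v = fd; s = psD[k - 1]; }
            cM[k] = lM(k - 1, a) + v; csM[k] = s;
            if (cM[k] > best) { best = cM[k]; bestStart = s; bestEnd = p + 1; }
        }
        for (int k = 0; k < L; ++k) {
            if (k == 0) { cI[k] = R_NegInf; csI[k] = 0; continue; }
            double fm = pM[k] + lt(k, 1);
            double fi = pI[k] + lt(k, 4);
            if (fm >= fi) { cI[k] = lI(k, a) + fm; csI[k] = psM[k]; }
            else          { cI[k] = lI(k, a) + fi; csI[k] = psI[k]; }
        }
        cI[L] = R_NegInf; csI[L] = 0;
        cD[0] = R_NegInf; csD[0] = 0;
        for (int k = 1; k <= L; ++k) {
            double fm = cM[k - 1] + lt(k - 1, 2);
            double fd = cD[k - 1] + lt(k - 1, 6);
            if (fm >= fd) { cD[k] = fm; csD[k] = csM[k - 1]; }
            else          { cD[k] = fd; csD[k] = csD[k - 1]; }
        }
        std::swap(pM, cM); std::swap(pI, cI); std::swap(pD, cD);
        std::swap(psM, csM); std::swap(psI, csI); std::swap(psD, csD);
    }

    return NumericVector::create(best, double(bestStart), double(bestEnd));
}
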