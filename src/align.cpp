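#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>
#include <algorithm>
using namespace Rcpp;

// End-gap-free ("fitting") alignment: the shorter sequence is placed in
// full within the longer one, whose unaligned overhangs are free. Within
// the aligned region substitutions and gaps each cost 1; the optimum
// minimizes total cost and, among co-optimal alignments, maximizes the
// number of matching columns. That pins down every reported number:
//   overlap   = matches + cost      (columns of the aligned region)
//   mismatch  = cost                (substitutions + internal gaps)
//   identity  = 100 * matches / overlap
// Ambiguous bases (anything outside A/C/G/T) never match.

static inline bool is_base(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
List overlap_align_cpp(std::string a, std::string b) {
    for (auto &c : a) c = (char) std::toupper((unsigned char) c);
    for (auto &c : b) c = (char) std::toupper((unsigned char) c);
    const bool swapped = a.size() > b.size();
    const std::string &x = swapped ? b : a;   // shorter: fully consumed
    const std::string &y = swapped ? a : b;   // longer: free end gaps
    const int n = (int) x.size(), m = (int) y.size();
    const int W = m + 1;

    const int INF = n + m + 10;
    std::vector<int> C((size_t)(n + 1) * W, 0);   // cost
    std::vector<int> M((size_t)(n + 1) * W, 0);   // matches on best path
    std::vector<signed char> TB((size_t)(n + 1) * W, 0); // 1 diag, 2 up, 3 left
    for (int i = 1; i <= n; ++i) { C[(size_t) i * W] = i; TB[(size_t) i * W] = 2; }

    for (int i = 1; i <= n; ++i) {
        const char xi = x[i - 1];
        for (int j = 1; j <= m; ++j) {
            const bool hit = (xi == y[j - 1]) && is_base(xi);
            int c = C[(size_t)(i - 1) * W + (j - 1)] + (hit ? 0 : 1);
            int mm = M[(size_t)(i - 1) * W + (j - 1)] + (hit ? 1 : 0);
            signed char t = 1;
            int c2 = C[(size_t)(i - 1) * W + j] + 1;       // x char vs gap
            int m2 = M[(size_t)(i - 1) * W + j];
            if (c2 < c || (c2 == c && m2 > mm)) { c = c2; mm = m2; t = 2; }
            int c3 = C[(size_t) i * W + (j - 1)] + 1;      // y char vs gap
            int m3 = M[(size_t) i * W + (j - 1)];
            if (c3 < c || (c3 == c && m3 > mm)) { c = c3; mm = m3; t = 3; }
            C[(size_t) i * W + j] = c;
            M[(size_t) i * W + j] = mm;
            TB[(size_t) i * W + j] = t;
        }
    }

    // best end on the last row (trailing part of y is free); smallest j wins ties
    int bj = 0, bc = INF, bm = -1;
    for (int j = 0; j <= m; ++j) {
        int c = C[(size_t) n * W + j], mm = M[(size_t) n * W + j];
        if (c < bc || (c == bc && mm > bm)) { bc = c; bm = mm; bj = j; }
    }

    std::string xa, ya;
    int i = n, j = bj;
    while (i > 0) {
        signed char t = (j > 0) ? TB[(size_t) i * W + j] : 2;
        if (t == 1) { xa.push_back(x[i - 1]); ya.push_back(y[j - 1]); --i; --j; }
        else if (t == 2) { xa.push_back(x[i - 1]); ya.push_back('-'); --i; }
        else { xa.push_back('-'); ya.push_back(y[j - 1]); --j; }
    }
    const int x_start = 0, y_start = j;   // 0-based starts of the overlap
    std::reverse(xa.begin(), xa.end());
    std::reverse(ya.begin(), ya.end());

    const int cols = bm + bc;
    double identity = cols > 0 ? 100.0 * (double) bm / (double) cols : NA_REAL;

    IntegerVector mpos;
    {
        std::vector<int> v;
        for (int k = 0; k < (int) xa.size(); ++k) {
            char p = xa[k], q = ya[k];
            if (!(p == q && is_base(p))) v.push_back(k);
        }
        mpos = wrap(v);
    }

    return List::create(
        _["matches"] = bm,
        _["overlap_bp"] = cols,
        _["mismatches"] = bc,
        _["identity_pct"] = identity,
        _["a_start"] = swapped ? y_start : x_start,
        _["b_start"] = swapped ? x_start : y_start,
        _["a_aln"] = swapped ? ya : xa,
        _["b_aln"] = swapped ? xa : ya,
        _["mismatch_positions"] = mpos);
}
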