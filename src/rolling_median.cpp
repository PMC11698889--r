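#include <Rcpp.h>
#include <algorithm>
#include <vector>

// median of v[0..n), destroys order
static double med_inplace(std::vector<double>& v) {
    const size_t n = v.size();
    std::sort(v.begin(), v.end());
    if (n % 2 == 1) return v[n / 2];
    return (v[n / 2 - 1] + v[n / 2]) / 2.0;
}

// Rolling-median despike: a pixel deviating from its size x size window
// median by more than k times the scaled MAD (1.4826 * MAD) is replaced by
// that median. Windows are truncated at the image border (no padding).
// [[Rcpp::export(name = ".rolling_median_cpp")]]
Rcpp::NumericMatrix rolling_median_cpp(Rcpp::NumericMatrix x, int size,
                                       double k) {
    const int nr = x.nrow(), nc = x.ncol(), h = size / 2;
    Rcpp::NumericMatrix out = Rcpp::clone(x);
    std::vector<double> win, dev;
    win.reserve((size_t)size * size);
    dev.reserve((size_t)size * size);
    for (int j = 0; j < nc; ++j) {
        const int c0 = std::max(0, j - h), c1 = std::min(nc - 1, j + h);
        for (int i = 0; i < nr; ++i) {
            const int r0 = std::max(0, i - h), r1 = std::min(nr - 1, i + h);
            win.clear();
            for (int jj = c0; jj <= c1; ++jj)
                for (int ii = r0; ii <= r1; ++ii)
                    win.push_back(x(ii, jj));
            dev = win;
            const double m = med_inplace(dev);
            for (size_t t = 0; t < win.size(); ++t)
                dev[t] = std::abs(win[t] - m);
            const double s = 1.4826 * med_inplace(dev);
            if (std::abs(x(i, j) - m) > k * s) out(i, j) = m;
        }
    }
    return out;
}
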