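#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <limits>
#include <map>
#include <utility>
#include <vector>

// Exact gene-permutation p-value for the positive enrichment score of
// unweighted GSEA.
//
// The running sum over a ranked list of n genes, m of which belong to the
// tested set, steps by +1/m at a member and -1/(n-m) at a non-member.
// Rescaling by m(n-m) makes every prefix an integer: after j genes with h
// members seen, the prefix equals h*(n-m) - (j-h)*m = h*n - j*m.  The null
// places the m members uniformly among the n positions; the p-value is
//
//   p = Pr( max_k prefix_k >= T ),   T = round(ES+ * m * (n-m)).
//
// A lattice-path DP counts the arrangements whose prefixes all stay <= T-1:
// f[j][h] = [h*n - j*m <= T-1] * (f[j-1][h-1] + f[j-1][h]).  Counts reach
// C(n,m), far past 2^53, so rows hold little-endian base-2^32 big integers
// (addition is the only operation the DP needs).

namespace {

typedef std::vector<uint32_t> Big;

// flat (m+1) x L limb workspace: row h lives at buf[h*L], with len[h] limbs
void count_bounded(int n, int m, long long bound,
                   std::vector<uint32_t>& buf, std::vector<int>& len, int L,
                   Big& out) {
    std::fill(buf.begin(), buf.end(), 0u);
    std::fill(len.begin(), len.end(), 0);
    buf[0] = 1u;
    len[0] = 1;
    for (int j = 1; j <= n; ++j) {
        const int hmax = std::min(j, m);
        for (int h = hmax; h >= 0; --h) {  // descending: row h-1 still at j-1
            uint32_t* a = &buf[static_cast<size_t>(h) * L];
            const long long pref =
                static_cast<long long>(h) * n - static_cast<long long>(j) * m;
            if (pref > bound) {
                for (int i = 0; i < len[h]; ++i) a[i] = 0u;
                len[h] = 0;
                continue;
            }
            if (h == 0) continue;  // miss step leaves the count unchanged
            const int lb = len[h - 1];
            if (lb == 0) continue;
            const uint32_t* b = &buf[static_cast<size_t>(h - 1) * L];
            int lm = std::max(len[h], lb);
            uint64_t carry = 0;
            for (int i = 0; i < lm; ++i) {
                const uint64_t s =
                    static_cast<uint64_t>(a[i]) + b[i] + carry;
                a[i] = static_cast<uint32_t>(s);
                carry = s >> 32;
            }
            if (carry) a[lm++] = static_cast<uint32_t>(carry);
            len[h] = lm;
        }
    }
    const uint32_t* r = &buf[static_cast<size_t>(m) * L];
    out.assign(r, r + len[m]);
}

// a - b for a >= b, normalized (no leading zero limbs)
Big big_sub(const Big& a, const Big& b) {
    Big r(a.size(), 0u);
    int64_t borrow = 0;
    for (size_t i = 0; i < a.size(); ++i) {
        int64_t s = static_cast<int64_t>(a[i]) - borrow -
                    static_cast<int64_t>(i < b.size() ? b[i] : 0u);
        if (s < 0) {
            s += (static_cast<int64_t>(1) << 32);
            borrow = 1;
        } else {
            borrow = 0;
        }
        r[i] = static_cast<uint32_t>(s);
    }
    while (!r.empty() && r.back() == 0u) r.pop_back();
    return r;
}

// top three limbs (>= 96 bits) as mantissa * 2^e2: ample for 1e-15 ratios
double big_top(const Big& x, int& e2) {
    if (x.empty()) {
        e2 = 0;
        return 0.0;
    }
    const int top = static_cast<int>(x.size()) - 1;
    const int lo = std::max(0, top - 2);
    double mant = 0.0;
    for (int i = top; i >= lo; --i) mant = mant * 4294967296.0 + x[i];
    e2 = 32 * lo;
    return mant;
}

double big_ratio(const Big& num, const Big& den) {
    int en = 0, ed = 0;
    const double mn = big_top(num, en);
    const double md = big_top(den, ed);
    if (mn == 0.0) return 0.0;
    return std::ldexp(mn / md, en - ed);
}

// C(n,m) cache: the unconstrained DP count, reused across thresholds
const Big& total_arrangements(int n, int m, std::vector<uint32_t>& buf,
                              std::vector<int>& len, int L) {
    static std::map<std::pair<int, int>, Big> cache;
    const std::pair<int, int> key(n, m);
    std::map<std::pair<int, int>, Big>::iterator it = cache.find(key);
    if (it != cache.end()) return it->second;
    Big tot;
    count_bounded(n, m, static_cast<long long>(m) * (n - m), buf, len, L, tot);
    return cache.insert(std::make_pair(key, tot)).first->second;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".dpTailPvalue")]]
double dpTailPvalue(int n, int m, double threshold) {
    if (n < 2 || m < 1 || m > n - 1)
        Rcpp::stop("m must satisfy 1 <= m <= n - 1 (got n=%d, m=%d)", n, m);
    const double tr = std::floor(threshold + 0.5);
    if (std::fabs(threshold - tr) > 1e-6)
        Rcpp::stop("threshold must be (numerically) an integer");
    const long long T = static_cast<long long>(tr);
    const long long maxPref = static_cast<long long>(m) * (n - m);
    if (T <= 0) return 1.0;   // max prefix is always >= 0 (total sum is 0)
    if (T > maxPref) return 0.0;

    const int L = n / 32 + 3;  // C(n,m) < 2^n
    std::vector<uint32_t> buf(static_cast<size_t>(m + 1) * L, 0u);
    std::vector<int> len(m + 1, 0);

    const Big total = total_arrangements(n, m, buf, len, L);
    Big below;  // arrangements with every prefix <= T-1
    count_bounded(n, m, T - 1, buf, len, L, below);
    const Big atLeast = big_sub(total, below);
    double p = big_ratio(atLeast, total);
    if (p <= 0.0) p = std::numeric_limits<double>::min();
    if (p > 1.0) p = 1.0;
    return p;
}
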