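#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Canonical pairs AU/UA, GC/CG, GU/UG on 0=A,1=C,2=G,3=U encoding
static inline bool can_pair(int a, int b) {
    if (a < 0 || b < 0) return false;
    int x = a + b;
    return (x == 3 && a != b)        // A-U (0+3) or C-G (1+2)
        || (a == 2 && b == 3) || (a == 3 && b == 2); // G-U wobble
}

static std::vector<int> encode_rna(const std::string& s) {
    std::vector<int> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        switch (s[i]) {
        case 'A': case 'a': v[i] = 0; break;
        case 'C': case 'c': v[i] = 1; break;
        case 'G': case 'g': v[i] = 2; break;
        case 'U': case 'u': case 'T': case 't': v[i] = 3; break;
        default:
            stop("invalid character '%s' at position %d",
                 std::string(1, s[i]).c_str(), (int)i + 1);
        }
    }
    return v;
}

// Maximum base-pairing structure (Nussinov) with a minimum hairpin size.
// Deterministic traceback: prefer leaving i unpaired, else smallest partner j.
//' @noRd
// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_hairpin) {
    std::vector<int> s = encode_rna(seq);
    int n = (int)s.size();
    int h = min_hairpin;
    std::vector<std::vector<int>> M(n + 1, std::vector<int>(n + 1, 0));
    // M[i][j] over 1-based closed interval [i, j]
    for (int len = h + 2; len <= n; ++len) {
        for (int i = 1; i + len - 1 <= n; ++i) {
            int j = i + len - 1;
            int best = M[i + 1][j];
            for (int k = i + h + 1; k <= j; ++k) {
                if (!can_pair(s[i - 1], s[k - 1])) continue;
                int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
                int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
                int v = 1 + inner + outer;
                if (v > best) best = v;
            }
            M[i][j] = best;
        }
    }
    // traceback
    std::string db(n, '.');
    std::vector<std::pair<int, int>> pairs;
    std::vector<std::pair<int, int>> stack;
    stack.push_back(std::make_pair(1, n));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j || j - i < h + 1) continue;
        if (M[i][j] == M[i + 1][j]) { // prefer i unpaired
            stack.push_back(std::make_pair(i + 1, j));
            continue;
        }
        for (int k = i + h + 1; k <= j; ++k) {
            if (!can_pair(s[i - 1], s[k - 1])) continue;
            int inner = (k - 1 >= i + 1) ? M[i + 1][k - 1] : 0;
            int outer = (k + 1 <= j) ? M[k + 1][j] : 0;
            if (1 + inner + outer == M[i][j]) { // smallest such k
                db[i - 1] = '('; db[k - 1] = ')';
                pairs.push_back(std::make_pair(i, k));
                stack.push_back(std::make_pair(k + 1, j));
                stack.push_back(std::make_pair(i + 1, k - 1));
                break;
            }
        }
    }
    IntegerMatrix pm(pairs.size(), 2);
    for (size_t p = 0; p < pairs.size(); ++p) {
        pm(p, 0) = pairs[p].first; pm(p, 1) = pairs[p].second;
    }
    return List::create(_["structure"] = db, _["pairs"] = pm,
                        _["n_pairs"] = M[1][n]);
}

// Partition function over all pseudoknot-free structures with a constant
// energy per pair (McCaskill-style inside/outside on the simple model).
// Returns the base-pair probability matrix.
//' @noRd
// [[Rcpp::export(name = ".mccaskill_cpp")]]
List mccaskill_cpp(std::string seq, double pair_energy, double kT,
                   int min_hairpin) {
    std::vector<int> s = encode_rna(seq);
    int n = (int)s.size();
    int h = min_hairpin;
    double w = std::exp(-pair_energy / kT);

    // Inside: Q[i][j] = sum of Boltzmann weights over structures on [i, j],
    // 1-based, Q = 1 on empty/short intervals.
    std::vector<std::vector<double>> Q(n + 2, std::vector<double>(n + 2, 1.0));
    for (int len = 2; len <= n; ++len) {
        for (int i = 1; i + len - 1 <= n; ++i) {
            int j = i + len - 1;
            double q = Q[i + 1][j]; // i unpaired
            for (int k = i + h + 1; k <= j; ++k) {
                if (!can_pair(s[i - 1], s[k - 1])) continue;
                double inner = (k - 1 >= i + 1) ? Q[i + 1][k - 1] : 1.0;
                double outer = (k + 1 <= j) ? Q[k + 1][j] : 1.0;
                q += w * inner * outer;
            }
            Q[i][j] = q;
            if (!R_finite(q))
                stop("partition function overflow at length %d; shorten the sequence or raise kT", n);
        }
    }
    double Qtot = Q[1][n];

    // Outside: O[i][j] = weight of all exterior configurations given (i,j)
    // paired (excluding the w of (i,j) itself); recursion over the innermost
    // enclosing pair (p,q):
    //   O(i,j) = Q(1,i-1) Q(j+1,n)
    //          + sum_{p<i} Q(p+1,i-1) * T(p,j),
    //   T(p,j) = sum_{q>j, pair(p,q)} w O(p,q) Q(j+1,q-1)
    // Rows of O are completed in increasing i, so T(p,.) is available for p<i.
    auto Qin = [&](int i, int j) -> double { // inside weight, 1 if empty
        if (i > j) return 1.0;
        return Q[i][j];
    };
    std::vector<std::vector<double>> O(n + 1, std::vector<double>(n + 1, 0.0));
    std::vector<std::vector<double>> T(n + 1, std::vector<double>(n + 1, 0.0));
    NumericMatrix P(n, n);
    for (int i = 1; i <= n; ++i) {
        for (int j = i + h + 1; j <= n; ++j) {
            if (!can_pair(s[i - 1], s[j - 1])) continue;
            double o = Qin(1, i - 1) * Qin(j + 1, n);
            for (int p = 1; p < i; ++p)
                if (T[p][j] != 0.0) o += Qin(p + 1, i - 1) * T[p][j];
            O[i][j] = o;
            double pij = w * Qin(i + 1, j - 1) * o / Qtot;
            P(i - 1, j - 1) = pij; P(j - 1, i - 1) = pij;
        }
        // row i of O is final: accumulate T(i, j) for all j
        for (int j = 1; j <= n; ++j) {
            double t = 0.0;
            for (int q = j + 1; q <= n; ++q)
                if (O[i][q] != 0.0) t += w * O[i][q] * Qin(j + 1, q - 1);
            T[i][j] = t;
        }
    }
    return List::create(_["P"] = P, _["Qtot"] = Qtot);
}
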