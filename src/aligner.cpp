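#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding; -1 for non-ACGT (never seeds)
static inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
    }
}

static inline char rcbase(char c) {
    switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': case 'U': case 'u': return 'A';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = rcbase(c);
    return r;
}

// Banded Needleman-Wunsch alignment of a (the read) against b.
// Band is centred on the main diagonal with half-width `band`.
// In `fit` mode end-gaps in b are free (global in a, local in b), the
// convention for fitting a read into a reference window: identity then
// counts only the columns of the fitted region.
// Returns score, matches, columns, read bases aligned to ref bases.
struct AlnResult {
    double score;
    int matches;
    int columns;
    int read_aligned; // read bases opposite a reference base
};

static const double NEG_INF = -1e18;

static AlnResult banded_nw(const std::string& a, const std::string& b,
                           int band, double match, double mismatch,
                           double gap, bool fit) {
    int m = (int)a.size(), n = (int)b.size();
    // band must at least cover the length difference for a global path
    int w = band + std::abs(n - m);
    // DP over offsets: for row i, columns j in [i-w, i+w]
    int width = 2 * w + 1;
    std::vector<double> prev(width, NEG_INF), cur(width, NEG_INF);
    // traceback (0=diag, 1=up/gap in b, 2=left/gap in a, 3=free start)
    std::vector<uint8_t> tb((size_t)(m + 1) * width, 0);

    auto idx = [&](int i, int j) { return j - i + w; }; // column offset in band

    // row 0
    for (int j = 0; j <= std::min(n, w); ++j) {
        prev[idx(0, j)] = fit ? 0.0 : gap * j;
        tb[(size_t)0 * width + idx(0, j)] = fit ? 3 : 2;
    }
    for (int i = 1; i <= m; ++i) {
        std::fill(cur.begin(), cur.end(), NEG_INF);
        int jlo = std::max(0, i - w), jhi = std::min(n, i + w);
        for (int j = jlo; j <= jhi; ++j) {
            double best = NEG_INF; uint8_t dir = 0;
            if (j == 0) {
                best = gap * i; dir = 1;
            } else {
                // diagonal (i-1, j-1): same band offset, always in band
                double sc = prev[idx(i - 1, j - 1)];
                if (sc > NEG_INF / 2) {
                    double s = sc + (base2bit(a[i - 1]) == base2bit(b[j - 1])
                                     && base2bit(a[i - 1]) >= 0
                                     ? match : mismatch);
                    if (s > best) { best = s; dir = 0; }
                }
                if (j - (i - 1) <= w) { // up (i-1, j) in band
                    sc = prev[idx(i - 1, j)];
                    if (sc > NEG_INF / 2 && sc + gap > best) { best = sc + gap; dir = 1; }
                }
                if ((j - 1) - i >= -w) { // left (i, j-1) in band
                    sc = cur[idx(i, j - 1)];
                    if (sc > NEG_INF / 2 && sc + gap > best) { best = sc + gap; dir = 2; }
                }
            }
            cur[idx(i, j)] = best;
            tb[(size_t)i * width + idx(i, j)] = dir;
        }
        std::swap(prev, cur);
    }

    // end cell: (m, n) globally; in fit mode the best in-band cell of the
    // last row (smallest j on ties, for determinism)
    int jend = n;
    if (fit) {
        double best = NEG_INF;
        for (int j = std::max(0, m - w); j <= std::min(n, m + w); ++j) {
            if (prev[idx(m, j)] > best) { best = prev[idx(m, j)]; jend = j; }
        }
    }
    AlnResult res; res.score = prev[idx(m, jend)];
    res.matches = 0; res.columns = 0; res.read_aligned = 0;
    // traceback (free end-gaps in b contribute no columns)
    int i = m, j = jend;
    while (i > 0 || (!fit && j > 0)) {
        uint8_t dir = tb[(size_t)i * width + idx(i, j)];
        if (dir == 3) break;
        if (i > 0 && j > 0 && dir == 0) {
            res.columns++; res.read_aligned++;
            if (base2bit(a[i - 1]) == base2bit(b[j - 1]) && base2bit(a[i - 1]) >= 0)
                res.matches++;
            --i; --j;
        } else if (i > 0 && (dir == 1 || j == 0)) {
            res.columns++; --i;
        } else {
            res.columns++; --j;
        }
    }
    return res;
}

//' @noRd
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, int band,
                  double match, double mismatch, double gap, bool fit) {
    AlnResult r = banded_nw(a, b, band, match, mismatch, gap, fit);
    return List::create(_["score"] = r.score,
                        _["matches"] = r.matches,
                        _["columns"] = r.columns,
                        _["read_aligned"] = r.read_aligned,
                        _["identity"] = r.columns > 0 ? (double)r.matches / r.columns : 0.0,
                        _["coverage"] = a.size() > 0 ? (double)r.read_aligned / a.size() : 0.0);
}

struct KmerIndex {
    int k;
    std::unordered_map<uint64_t, std::vector<uint64_t>> map; // packed (ref<<32)|pos
};

static void index_refs(const std::vector<std::string>& refs, int k, KmerIndex& ix) {
    ix.k = k;
    uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (size_t r = 0; r < refs.size(); ++r) {
        const std::string& s = refs[r];
        if ((int)s.size() < k) continue;
        uint64_t km = 0; int run = 0;
        for (size_t p = 0; p < s.size(); ++p) {
            int b = base2bit(s[p]);
            if (b < 0) { run = 0; km = 0; continue; }
            km = ((km << 2) | (uint64_t)b) & mask;
            if (++run >= k)
                ix.map[km].push_back(((uint64_t)r << 32) | (uint64_t)(p - k + 1));
        }
    }
}

struct Hit {
    bool found = false;
    int ref = -1;
    double identity = 0, coverage = 0, score = 0;
    int strand = 0; // 0 = '+', 1 = '-'
};

// Align one read (already oriented) against candidate windows found by seeding.
static void seed_and_score(const std::string& read, int strand,
                           const std::vector<std::string>& refs,
                           const KmerIndex& ix, int band,
                           double match, double mismatch, double gap,
                           Hit& best) {
    int k = ix.k;
    int L = (int)read.size();
    if (L < k) return;
    uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    // votes per (ref, diagonal)
    std::unordered_map<uint64_t, int> votes; // key: (ref<<32) | (diag + L)
    uint64_t km = 0; int run = 0;
    for (int q = 0; q < L; ++q) {
        int b = base2bit(read[q]);
        if (b < 0) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint64_t)b) & mask;
        if (++run >= k) {
            auto it = ix.map.find(km);
            if (it == ix.map.end()) continue;
            for (uint64_t packed : it->second) {
                int r = (int)(packed >> 32);
                int p = (int)(packed & 0xffffffffULL);
                int diag = p - (q - k + 1);
                votes[((uint64_t)r << 32) | (uint64_t)(diag + L)]++;
            }
        }
    }
    if (votes.empty()) return;
    // best diagonal per reference (max votes, then smallest diagonal)
    std::unordered_map<int, std::pair<int, int>> per_ref; // ref -> (votes, diag)
    for (auto& kv : votes) {
        int r = (int)(kv.first >> 32);
        int diag = (int)(kv.first & 0xffffffffULL) - L;
        auto it = per_ref.find(r);
        if (it == per_ref.end() || kv.second > it->second.first ||
            (kv.second == it->second.first && diag < it->second.second))
            per_ref[r] = std::make_pair(kv.second, diag);
    }
    std::vector<int> cand;
    for (auto& kv : per_ref) cand.push_back(kv.first);
    std::sort(cand.begin(), cand.end()); // deterministic evaluation order
    for (int r : cand) {
        int diag = per_ref[r].second;
        const std::string& ref = refs[r];
        int s0 = std::max(0, diag - band);
        int e0 = std::min((int)ref.size(), diag + L + band);
        if (e0 <= s0) continue;
        AlnResult a = banded_nw(read, ref.substr(s0, e0 - s0), band,
                                match, mismatch, gap, true);
        // strictly better score wins; ties keep earlier (smaller ref id, '+')
        if (!best.found || a.score > best.score) {
            best.found = true; best.ref = r; best.score = a.score;
            best.identity = a.columns > 0 ? (double)a.matches / a.columns : 0.0;
            best.coverage = (double)a.read_aligned / L;
            best.strand = strand;
        }
    }
}

// Batch alignment: best hit per read over both strands.
// refs must be supplied in the desired tie-break (lexicographic id) order.
//' @noRd
// [[Rcpp::export(name = ".align_batch_cpp")]]
DataFrame align_batch_cpp(CharacterVector reads, CharacterVector refs,
                          int k, int band, double match, double mismatch,
                          double gap) {
    std::vector<std::string> refv(refs.size());
    for (int i = 0; i < refs.size(); ++i) refv[i] = as<std::string>(refs[i]);
    KmerIndex ix; index_refs(refv, k, ix);

    int n = reads.size();
    IntegerVector target(n, NA_INTEGER);
    NumericVector identity(n, NA_REAL), coverage(n, NA_REAL), score(n, NA_REAL);
    CharacterVector strand(n, NA_STRING);
    for (int i = 0; i < n; ++i) {
        std::string rd = as<std::string>(reads[i]);
        Hit best;
        seed_and_score(rd, 0, refv, ix, band, match, mismatch, gap, best);
        Hit bestrc;
        seed_and_score(revcomp(rd), 1, refv, ix, band, match, mismatch, gap, bestrc);
        if (bestrc.found && (!best.found || bestrc.score > best.score))
            best = bestrc; // '+' preferred on exact score tie
        if (best.found) {
            target[i] = best.ref + 1;
            identity[i] = best.identity;
            coverage[i] = best.coverage;
            score[i] = best.score;
            strand[i] = best.strand == 0 ? "+" : "-";
        }
    }
    return DataFrame::create(_["target"] = target, _["identity"] = identity,
                             _["coverage"] = coverage, _["score"] = score,
                             _["strand"] = strand,
                             _["stringsAsFactors"] = false);
}

// Substitution errors with R's RNG (deterministic under set.seed()).
//' @noRd
// [[Rcpp::export(name = ".mutate_reads_cpp")]]
CharacterVector mutate_reads_cpp(CharacterVector reads, double error_rate) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int n = reads.size();
    CharacterVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(reads[i]);
        for (size_t p = 0; p < s.size(); ++p) {
            if (unif_rand() < error_rate) {
                int cur = base2bit(s[p]);
                int nb = (int)(unif_rand() * 3.0);
                if (nb > 2) nb = 2;
                // pick uniformly among the three other bases
                int pick = (cur < 0) ? nb : (nb >= cur ? nb + 1 : nb);
                s[p] = bases[pick & 3];
            }
        }
        out[i] = s;
    }
    return out;
}

// Keep-length per read under sliding-window quality trimming:
// scanning 5'->3', cut before the first window whose mean quality < minq.
//' @noRd
// [[Rcpp::export(name = ".trim_lengths_cpp")]]
IntegerVector trim_lengths_cpp(CharacterVector quals, int window, double minq,
                               int offset) {
    int n = quals.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string q = as<std::string>(quals[i]);
        int L = (int)q.size();
        int keep = L;
        if (L >= window) {
            double sum = 0;
            for (int p = 0; p < window; ++p) sum += q[p] - offset;
            int s = 0;
            while (true) {
                if (sum / window < minq) { keep = s; break; }
                if (s + window >= L) break;
                sum += (q[s + window] - offset) - (q[s] - offset);
                ++s;
            }
        }
        out[i] = keep;
    }
    return out;
}
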