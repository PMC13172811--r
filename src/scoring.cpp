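#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Similarity and matching kernels.
//
// The match score between a probe and a read window is the indel ratio
//   100 * 2 * LCS(a, b) / (|a| + |b|)
// i.e. the normalised insertion/deletion edit distance (a substitution
// costs one deletion plus one insertion).  The partial ratio is the
// maximum indel ratio over every contiguous substring of the read; that
// exhaustive maximum is the contract, and the pruned production scorer
// below must agree with the naive scorer exactly.

static int lcs_len(const char* a, int la, const char* b, int lb) {
    // rolling one-row LCS; O(la*lb) time, O(la) space
    std::vector<int> dp(la + 1, 0);
    for (int j = 0; j < lb; ++j) {
        int prev_diag = 0; // dp_old[k-1]
        const char c = b[j];
        for (int k = 1; k <= la; ++k) {
            const int tmp = dp[k];
            if (a[k - 1] == c)
                dp[k] = prev_diag + 1;
            else if (dp[k - 1] > dp[k])
                dp[k] = dp[k - 1];
            prev_diag = tmp;
        }
    }
    return dp[la];
}

// [[Rcpp::export(name = ".indel_ratio_cpp")]]
double indel_ratio_cpp(const std::string& a, const std::string& b) {
    if (a.empty() || b.empty())
        stop("indel ratio requires non-empty sequences");
    const int l = lcs_len(a.c_str(), (int)a.size(), b.c_str(), (int)b.size());
    return 200.0 * l / (double)(a.size() + b.size());
}

// Production partial ratio: max over all contiguous substrings of `read`.
// For each start position the LCS row is extended one read character at a
// time (O(m) per window), and the window loop stops as soon as even a
// perfect LCS (= m) over the longer window could not beat the current
// best -- a bound that only discards provably suboptimal windows, so the
// result equals the exhaustive maximum.
static double partial_ratio_impl(const std::string& probe, const std::string& read) {
    const int m = (int)probe.size();
    const int n = (int)read.size();
    if (read.find(probe) != std::string::npos)
        return 100.0; // exact substring: the maximum is attained
    double best = 0.0;
    std::vector<int> dp(m + 1);
    for (int i = 0; i < n; ++i) {
        std::fill(dp.begin(), dp.end(), 0);
        for (int j = i; j < n; ++j) {
            const int w = j - i + 1;
            // upper bound over this and all longer windows from start i
            if (200.0 * m <= best * (m + w))
                break;
            int prev_diag = 0;
            const char c = read[j];
            for (int k = 1; k <= m; ++k) {
                const int tmp = dp[k];
                if (probe[k - 1] == c)
                    dp[k] = prev_diag + 1;
                else if (dp[k - 1] > dp[k])
                    dp[k] = dp[k - 1];
                prev_diag = tmp;
            }
            const double r = 200.0 * dp[m] / (double)(m + w);
            if (r > best)
                best = r;
        }
    }
    return best;
}

// [[Rcpp::export(name = ".partial_ratio_cpp")]]
double partial_ratio_cpp(const std::string& probe, const std::string& read) {
    if (probe.empty() || read.empty())
        stop("partial ratio requires non-empty sequences");
    if ((int)read.size() < (int)probe.size())
        stop("read is shorter than the probe; caller must exclude short reads");
    return partial_ratio_impl(probe, read);
}

// Reference scorer: every substring scored with a fresh full DP, no
// shortcut, no pruning.  Kept deliberately naive and structurally
// independent of the production path.
// [[Rcpp::export(name = ".partial_ratio_naive_cpp")]]
double partial_ratio_naive_cpp(const std::string& probe, const std::string& read) {
    if (probe.empty() || read.empty())
        stop("partial ratio requires non-empty sequences");
    const int m = (int)probe.size();
    const int n = (int)read.size();
    double best = 0.0;
    for (int i = 0; i < n; ++i) {
        for (int j = i; j < n; ++j) {
            const int w = j - i + 1;
            const int l = lcs_len(probe.c_str(), m, read.c_str() + i, w);
            const double r = 200.0 * l / (double)(m + w);
            if (r > best)
                best = r;
        }
    }
    return best;
}

static char complement_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    case 'S': return 'S'; case 'W': return 'W';
    case 'N': return 'N';
    default:  return 'N'; // unknown read characters complement to N
    }
}

static std::string revcomp(const std::string& s) {
    std::string out(s.rbegin(), s.rend());
    for (size_t i = 0; i < out.size(); ++i)
        out[i] = complement_base(out[i]);
    return out;
}

// Score a batch of reads against a panel.
//
// expansions: list (one element per probe) of character vectors with the
// probe's unambiguous expansions; probe_len: integer vector of probe
// lengths.  Each read is compared on both strands (the minus strand
// compares expansions against the reverse complement of the read); the
// probe score is the maximum over expansions and strands.  Reads shorter
// than a probe are excluded from that probe (score NA).  Returns a list
// with a numeric score matrix (reads x probes) and a character strand
// matrix ("+"/"-", "+" on ties).
// [[Rcpp::export(name = ".score_batch_cpp")]]
List score_batch_cpp(CharacterVector reads, List expansions, IntegerVector probe_len) {
    const int nr = reads.size();
    const int np = expansions.size();
    NumericMatrix score(nr, np);
    CharacterMatrix strand(nr, np);

    std::vector<std::vector<std::string> > exp(np);
    for (int p = 0; p < np; ++p) {
        CharacterVector e = expansions[p];
        exp[p].reserve(e.size());
        for (int k = 0; k < e.size(); ++k)
            exp[p].push_back(as<std::string>(e[k]));
    }

    for (int i = 0; i < nr; ++i) {
        std::string fwd = as<std::string>(reads[i]);
        std::transform(fwd.begin(), fwd.end(), fwd.begin(), ::toupper);
        const std::string rev = revcomp(fwd);
        const int rl = (int)fwd.size();
        for (int p = 0; p < np; ++p) {
            if (rl < probe_len[p]) {
                score(i, p) = NA_REAL;
                strand(i, p) = NA_STRING;
                continue;
            }
            double best_plus = 0.0, best_minus = 0.0;
            for (size_t k = 0; k < exp[p].size(); ++k) {
                const std::string& e = exp[p][k];
                const double sp = partial_ratio_impl(e, fwd);
                if (sp > best_plus) best_plus = sp;
                if (best_plus >= 100.0) break; // cannot improve
                const double sm = partial_ratio_impl(e, rev);
                if (sm > best_minus) best_minus = sm;
            }
            if (best_plus < 100.0) {
                // finish minus-strand maximum if the plus loop broke early
                for (size_t k = 0; k < exp[p].size() && best_minus < 100.0; ++k) {
                    const double sm = partial_ratio_impl(exp[p][k], rev);
                    if (sm > best_minus) best_minus = sm;
                }
            }
            if (best_plus >= best_minus) {
                score(i, p) = best_plus;
                strand(i, p) = "+";
            } else {
                score(i, p) = best_minus;
                strand(i, p) = "-";
            }
        }
    }
    return List::create(_["score"] = score, _["strand"] = strand);
}
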