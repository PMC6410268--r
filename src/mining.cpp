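// Closed sequential pattern mining with single-residue wildcards.
//
// Patterns are contiguous motifs over the residue alphabet plus a wildcard
// ('.') that matches exactly one arbitrary residue. A pattern is admissible
// when its first and last items are residues and no run of consecutive
// wildcards exceeds max_wc. Support counts distinct sequences containing at
// least one occurrence. A frequent pattern is reported only when closed:
// no admissible proper super-pattern (flank extension or wildcard
// specialization) has the same support.
//
// Search: depth-first growth over projected occurrence lists (sequence id +
// end offset of each occurrence). Four exact prunings keep the search close
// to linear in the size of the closed set; each removes only branches all
// of whose patterns are provably non-closed:
//   * support pruning: |S_a| below threshold kills the branch;
//   * wildcard unanimity: appending a wildcard is skipped when every
//     surviving occurrence is followed by the same residue b, because any
//     pattern grown below that branch has an equal-support specialization
//     (the same pattern with b in place of the wildcard);
//   * left unanimity (BackScan): a branch dies when, for some gap j <=
//     max_wc, every occurrence has the same residue j+1 positions before
//     its start — every descendant then has an equal-support left
//     extension;
//   * retroactive wildcard check: a child whose occurrence set has become
//     unanimous at an existing wildcard position is skipped — every
//     descendant's occurrences agree there too, so the specialization is
//     an equal-support proper super of each of them.
//
// Closedness is decided at report time from the pattern's own occurrence
// list by testing every one-step super-pattern: prepend residue r plus j
// wildcards (j <= max_wc), append j wildcards plus residue r, or specialize
// one wildcard to a residue. Equality of support with any of them means not
// closed; a chain argument reduces arbitrary equal-support super-patterns
// to a sequence of such one-step supers, so the check is exact.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Occ {
  int s;  // sequence index, 0-based
  int e;  // offset just past the last matched character, 0-based
};

inline uint32_t charbit(char c) { return 1u << (c - 'A'); }

class Miner {
 public:
  Miner(const std::vector<std::string>& seqs, int thr, int min_non_wc,
        int max_wc, long long node_budget)
      : seqs_(seqs), thr_(thr), min_non_wc_(min_non_wc), max_wc_(max_wc),
        budget_(node_budget) {}

  void run() {
    // Roots: one per residue with enough supporting sequences. Occurrence
    // lists are built in (sequence, position) order and stay sorted.
    std::vector<std::vector<Occ>> rocc(26);
    for (int s = 0; s < (int)seqs_.size(); ++s)
      for (int i = 0; i < (int)seqs_[s].size(); ++i)
        rocc[seqs_[s][i] - 'A'].push_back({s, i + 1});
    std::string pat;
    for (int c = 0; c < 26; ++c) {
      if (rocc[c].empty() || support(rocc[c]) < thr_) continue;
      pat.assign(1, (char)('A' + c));
      dfs(pat, rocc[c], 1, 0);
    }
  }

  std::vector<std::string> pats;
  std::vector<int> sups;
  std::vector<std::vector<int>> ids;  // 1-based sequence indices

 private:
  const std::vector<std::string>& seqs_;
  int thr_, min_non_wc_, max_wc_;
  long long budget_;
  long long nodes_ = 0;

  static int support(const std::vector<Occ>& occ) {
    int n = 0, last = -1;
    for (const Occ& o : occ)
      if (o.s != last) { ++n; last = o.s; }
    return n;
  }

  // TRUE when every occurrence has the same residue at left gap j for some
  // j <= max_wc: the branch only contains non-closed patterns.
  bool left_forced(const std::string& pat, const std::vector<Occ>& occ) const {
    int plen = (int)pat.size();
    for (int j = 0; j <= max_wc_; ++j) {
      char u = 0;
      bool all = true;
      for (const Occ& o : occ) {
        int pos = o.e - plen - 1 - j;
        if (pos < 0) { all = false; break; }
        char c = seqs_[o.s][pos];
        if (u == 0) u = c;
        else if (u != c) { all = false; break; }
      }
      if (all) return true;
    }
    return false;
  }

  // TRUE when the occurrence set agrees at some wildcard position of pat:
  // every descendant then has an equal-support specialization.
  bool wildcard_forced(const std::string& pat,
                       const std::vector<Occ>& occ) const {
    int plen = (int)pat.size();
    for (int k = 0; k < plen; ++k) {
      if (pat[k] != '.') continue;
      char u = 0;
      bool all = true;
      for (const Occ& o : occ) {
        char c = seqs_[o.s][o.e - plen + k];
        if (u == 0) u = c;
        else if (u != c) { all = false; break; }
      }
      if (all) return true;
    }
    return false;
  }

  void dfs(std::string& pat, const std::vector<Occ>& occ, int non_wc,
           int trail) {
    if (++nodes_ > budget_)
      stop("pattern space too large (node budget exceeded); raise min_support or lower max_wc");
    if ((nodes_ & 0xFFFF) == 0) Rcpp::checkUserInterrupt();

    if (left_forced(pat, occ)) return;

    if (trail == 0 && non_wc >= min_non_wc_ && closed(pat, occ)) {
      pats.push_back(pat);
      sups.push_back(support(occ));
      std::vector<int> sup_ids;
      int last = -1;
      for (const Occ& o : occ)
        if (o.s != last) { sup_ids.push_back(o.s + 1); last = o.s; }
      ids.push_back(std::move(sup_ids));
    }

    // Tally next characters over surviving occurrences.
    std::vector<std::vector<Occ>> next(26);
    uint32_t seen = 0;
    int wc_support = 0, wc_last = -1;
    for (const Occ& o : occ) {
      const std::string& sq = seqs_[o.s];
      if (o.e >= (int)sq.size()) continue;
      int c = sq[o.e] - 'A';
      next[c].push_back({o.s, o.e + 1});
      seen |= 1u << c;
      if (o.s != wc_last) { ++wc_support; wc_last = o.s; }
    }

    for (int c = 0; c < 26; ++c) {
      if (next[c].empty() || support(next[c]) < thr_) continue;
      pat.push_back((char)('A' + c));
      if (!wildcard_forced(pat, next[c])) dfs(pat, next[c], non_wc + 1, 0);
      pat.pop_back();
    }

    // Wildcard growth: only when under the run limit, still frequent, and
    // the following residue is not unanimous (see header comment).
    if (trail < max_wc_ && wc_support >= thr_ &&
        (seen & (seen - 1)) != 0) {
      std::vector<Occ> wocc;
      wocc.reserve(occ.size());
      for (const Occ& o : occ)
        if (o.e < (int)seqs_[o.s].size()) wocc.push_back({o.s, o.e + 1});
      pat.push_back('.');
      if (!wildcard_forced(pat, wocc)) dfs(pat, wocc, non_wc, trail + 1);
      pat.pop_back();
    }
  }

  // Exact one-step closedness from the occurrence list.
  bool closed(const std::string& pat, const std::vector<Occ>& occ) const {
    int plen = (int)pat.size();
    // Right extensions: residue at offset e + j, j wildcards in between.
    for (int j = 0; j <= max_wc_; ++j) {
      uint32_t inter = ~0u;
      int i = 0, n = (int)occ.size();
      while (i < n && inter != 0) {
        int s = occ[i].s;
        uint32_t m = 0;
        for (; i < n && occ[i].s == s; ++i) {
          int pos = occ[i].e + j;
          if (pos < (int)seqs_[s].size()) m |= charbit(seqs_[s][pos]);
        }
        inter &= m;
      }
      if (i >= n && inter != 0) return false;
    }
    // Left extensions: residue at offset start - 1 - j.
    for (int j = 0; j <= max_wc_; ++j) {
      uint32_t inter = ~0u;
      int i = 0, n = (int)occ.size();
      while (i < n && inter != 0) {
        int s = occ[i].s;
        uint32_t m = 0;
        for (; i < n && occ[i].s == s; ++i) {
          int pos = occ[i].e - plen - 1 - j;
          if (pos >= 0) m |= charbit(seqs_[s][pos]);
        }
        inter &= m;
      }
      if (i >= n && inter != 0) return false;
    }
    // Wildcard specializations.
    for (int k = 0; k < plen; ++k) {
      if (pat[k] != '.') continue;
      uint32_t inter = ~0u;
      int i = 0, n = (int)occ.size();
      while (i < n && inter != 0) {
        int s = occ[i].s;
        uint32_t m = 0;
        for (; i < n && occ[i].s == s; ++i)
          m |= charbit(seqs_[s][occ[i].e - plen + k]);
        inter &= m;
      }
      if (i >= n && inter != 0) return false;
    }
    return true;
  }
};

inline bool match_at(const std::string& sq, int start, const std::string& pat) {
  for (int k = 0; k < (int)pat.size(); ++k)
    if (pat[k] != '.' && sq[start + k] != pat[k]) return false;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List mine_patterns_cpp(CharacterVector seqs, int min_support_abs,
                       int min_non_wc, int max_wc,
                       double node_budget = 2e8) {
  std::vector<std::string> sv(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) sv[i] = as<std::string>(seqs[i]);
  Miner m(sv, min_support_abs, min_non_wc, max_wc, (long long)node_budget);
  m.run();
  List idl(m.ids.size());
  for (size_t i = 0; i < m.ids.size(); ++i) idl[i] = wrap(m.ids[i]);
  return List::create(_["pattern"] = wrap(m.pats),
                      _["support"] = wrap(m.sups),
                      _["supporting"] = idl);
}

// Presence matrix: rows = sequences, columns = patterns; entry 1 when the
// sequence contains at least one occurrence of the pattern.
// [[Rcpp::export]]
IntegerMatrix match_patterns_cpp(CharacterVector patterns,
                                 CharacterVector seqs) {
  int np = patterns.size(), ns = seqs.size();
  std::vector<std::string> pv(np), sv(ns);
  for (int i = 0; i < np; ++i) pv[i] = as<std::string>(patterns[i]);
  for (int i = 0; i < ns; ++i) sv[i] = as<std::string>(seqs[i]);
  IntegerMatrix out(ns, np);
  for (int p = 0; p < np; ++p) {
    int m = (int)pv[p].size();
    for (int s = 0; s < ns; ++s) {
      int n = (int)sv[s].size();
      int hit = 0;
      for (int start = 0; start + m <= n; ++start)
        if (match_at(sv[s], start, pv[p])) { hit = 1; break; }
      out(s, p) = hit;
    }
  }
  return out;
}
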