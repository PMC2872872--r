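#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with traceback. Scores are integers on
// the caller's scale (match/mismatch typically +-100, gap_open/gap_extend
// positive penalties on the same scale). 'N' matches nothing: any column
// containing N scores as a mismatch and is never counted as a match.
// Returns 1-based inclusive coordinates on both sequences.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0);
  const int NEG = INT_MIN / 2;
  // H: best ending aligned at (i,j); E: gap in a (consume b); F: gap in b.
  // Full Gotoh traceback: tbH says which state delivered H, tbE/tbF say
  // whether the gap run opened here (from H) or extends.
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Ecur(m + 1, NEG),
      Fcol(m + 1, NEG);
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0),
      tbE((size_t)(n + 1) * (m + 1), 0), tbF((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Ecur[0] = NEG;
    Hcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      size_t at = (size_t)i * (m + 1) + j;
      char ca = a[i - 1], cb = b[j - 1];
      int s = (ca == cb && ca != 'N') ? match : mismatch;
      int diag = Hprev[j - 1] + s;
      int e_open = Hcur[j - 1] - gap_open, e_ext = Ecur[j - 1] - gap_extend;
      int e = std::max(e_open, e_ext);
      tbE[at] = e_open >= e_ext ? 1 : 0; // 1: opened from H
      int f_open = Hprev[j] - gap_open, f_ext = Fcol[j] - gap_extend;
      int f = std::max(f_open, f_ext);
      tbF[at] = f_open >= f_ext ? 1 : 0;
      Ecur[j] = e;
      Fcol[j] = f;
      int h = diag;
      unsigned char t = 1;
      if (f > h) { h = f; t = 2; }
      if (e > h) { h = e; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      Hcur[j] = h;
      tbH[at] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0)
    return List::create(_["score"] = 0);
  std::string aa, ab;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 2 = F (gap in b), 3 = E (gap in a)
  while (i > 0 && j > 0) {
    size_t at = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char t = tbH[at];
      if (t == 0) break;
      if (t == 1) {
        aa.push_back(a[i - 1]);
        ab.push_back(b[j - 1]);
        --i; --j;
      } else {
        state = t; // enter the gap state; emit on the next iterations
      }
    } else if (state == 2) { // F: consume a
      aa.push_back(a[i - 1]);
      ab.push_back('-');
      bool opened = tbF[at] == 1;
      --i;
      if (opened) state = 0;
    } else { // E: consume b
      aa.push_back('-');
      ab.push_back(b[j - 1]);
      bool opened = tbE[at] == 1;
      --j;
      if (opened) state = 0;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());
  int matches = 0, mism = 0, gapopens = 0, gapcols = 0;
  bool ingap = false;
  for (size_t k = 0; k < aa.size(); ++k) {
    if (aa[k] == '-' || ab[k] == '-') {
      ++gapcols;
      if (!ingap) { ++gapopens; ingap = true; }
    } else {
      ingap = false;
      if (aa[k] == ab[k] && aa[k] != 'N') ++matches; else ++mism;
    }
  }
  return List::create(
      _["score"] = best, _["a_start"] = i + 1, _["a_end"] = bi,
      _["b_start"] = j + 1, _["b_end"] = bj, _["aligned_a"] = aa,
      _["aligned_b"] = ab, _["matches"] = matches, _["mismatches"] = mism,
      _["gap_opens"] = gapopens, _["gap_cols"] = gapcols,
      _["length"] = (int)aa.size());
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (size_t k = 0; k < r.size(); ++k) {
      switch (r[k]) {
      case 'A': r[k] = 'T'; break;
      case 'C': r[k] = 'G'; break;
      case 'G': r[k] = 'C'; break;
      case 'T': r[k] = 'A'; break;
      case 'a': r[k] = 't'; break;
      case 'c': r[k] = 'g'; break;
      case 'g': r[k] = 'c'; break;
      case 't': r[k] = 'a'; break;
      default: break; // N and friends are self-complementary here
      }
    }
    out[i] = r;
  }
  out.attr("names") = x.attr("names");
  return out;
}

// Exhaustive ungapped scan of short signatures against target sequences on
// both strands, reporting every placement with at most max_mm substitutions
// over the full signature length. Positions are 0-based on the forward
// strand of the target ('-' hits report the start of the matched window on
// the forward strand). 'N' never matches.
// [[Rcpp::export]]
DataFrame map_srna_cpp(CharacterVector targets, CharacterVector signatures,
                       int max_mm) {
  std::vector<std::string> tg(targets.size());
  for (int i = 0; i < targets.size(); ++i) tg[i] = as<std::string>(targets[i]);
  std::vector<int> sig_idx, t_idx, pos, mmv;
  std::vector<std::string> strand;
  for (int s = 0; s < signatures.size(); ++s) {
    std::string q = as<std::string>(signatures[s]);
    std::string qr(q.rbegin(), q.rend());
    for (size_t k = 0; k < qr.size(); ++k) {
      switch (qr[k]) {
      case 'A': qr[k] = 'T'; break;
      case 'C': qr[k] = 'G'; break;
      case 'G': qr[k] = 'C'; break;
      case 'T': qr[k] = 'A'; break;
      default: break;
      }
    }
    const int L = q.size();
    for (int t = 0; t < (int)tg.size(); ++t) {
      const std::string &T = tg[t];
      const int M = (int)T.size() - L;
      for (int p = 0; p <= M; ++p) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          char c = T[p + k];
          if (c != q[k] || c == 'N') { if (++mm > max_mm) break; }
        }
        if (mm <= max_mm) {
          sig_idx.push_back(s + 1); t_idx.push_back(t + 1);
          pos.push_back(p); mmv.push_back(mm); strand.push_back("+");
        }
        mm = 0;
        for (int k = 0; k < L; ++k) {
          char c = T[p + k];
          if (c != qr[k] || c == 'N') { if (++mm > max_mm) break; }
        }
        if (mm <= max_mm) {
          sig_idx.push_back(s + 1); t_idx.push_back(t + 1);
          pos.push_back(p); mmv.push_back(mm); strand.push_back("-");
        }
      }
    }
  }
  return DataFrame::create(_["sig_idx"] = sig_idx, _["target_idx"] = t_idx,
                           _["position"] = pos, _["strand"] = strand,
                           _["mismatches"] = mmv,
                           _["stringsAsFactors"] = false);
}

// Verify a candidate read-vs-read overlap at a fixed offset of b relative to
// a (b starts at position 'off' in a's coordinates; off may be negative).
// Returns the overlap span and mismatch count, or span 0 if below min_ov.
// [[Rcpp::export]]
IntegerVector overlap_at_cpp(std::string a, std::string b, int off,
                             int min_ov) {
  const int la = a.size(), lb = b.size();
  int lo = std::max(0, off), hi = std::min(la, off + lb);
  int span = hi - lo;
  if (span < min_ov) return IntegerVector::create(0, 0);
  int mm = 0;
  for (int p = lo; p < hi; ++p) {
    char ca = a[p], cb = b[p - off];
    if (ca != cb || ca == 'N') ++mm;
  }
  return IntegerVector::create(span, mm);
}

// Candidate generation + verification for the read overlap graph. fwd and
// rcv are the forward and reverse-complement read strings. Candidate
// offsets come from shared exact k-mers; a candidate becomes an edge when
// the implied dovetail/containment overlap spans >= k and its full region
// identity is >= region_identity. One edge is kept per read pair: largest
// overlap, then smallest |offset|.
// [[Rcpp::export]]
DataFrame overlap_edges_cpp(CharacterVector fwd, CharacterVector rcv,
                            int k, double region_identity) {
  const int n = fwd.size();
  std::vector<std::string> F(n), R(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    F[i] = as<std::string>(fwd[i]);
    R[i] = as<std::string>(rcv[i]);
    len[i] = F[i].size();
  }
  struct Entry { int read; int pos; bool rev; };
  std::unordered_map<std::string, std::vector<Entry>> buckets;
  for (int i = 0; i < n; ++i) {
    for (int rev = 0; rev < 2; ++rev) {
      const std::string &s = rev ? R[i] : F[i];
      for (int p = 0; p + k <= (int)s.size(); ++p) {
        std::string w = s.substr(p, k);
        if (w.find('N') != std::string::npos) continue;
        buckets[w].push_back({i, p, rev == 1});
      }
    }
  }
  std::unordered_set<uint64_t> seen;
  struct Best { int span, off; bool opposite; bool set; };
  std::unordered_map<uint64_t, Best> best;
  for (auto &kv : buckets) {
    auto &v = kv.second;
    const int m = v.size();
    if (m < 2) continue;
    for (int a = 0; a < m; ++a) {
      for (int b = 0; b < m; ++b) {
        int i = v[a].read, j = v[b].read;
        if (i >= j) continue;
        // offset of the oriented-j string in the frame the word was found
        // in, then mirrored to the i-forward frame if needed
        int off0 = v[a].pos - v[b].pos;
        int off = v[a].rev ? len[i] - off0 - len[j] : off0;
        bool opposite = v[a].rev != v[b].rev;
        uint64_t key = ((uint64_t)i << 44) | ((uint64_t)j << 24) |
                       ((uint64_t)(opposite ? 1 : 0) << 23) |
                       (uint64_t)(off + (1 << 22));
        if (!seen.insert(key).second) continue;
        int lo = std::max(0, off), hi = std::min(len[i], off + len[j]);
        int span = hi - lo;
        if (span < k) continue;
        int allowed = (int)std::floor((1.0 - region_identity) * span);
        const std::string &A = F[i];
        const std::string &B = opposite ? R[j] : F[j];
        int mm = 0;
        for (int p = lo; p < hi; ++p) {
          char ca = A[p], cb = B[p - off];
          if (ca != cb || ca == 'N') { if (++mm > allowed) break; }
        }
        if (mm > allowed) continue;
        uint64_t pkey = ((uint64_t)i << 22) | (uint64_t)j;
        auto it = best.find(pkey);
        if (it == best.end() || span > it->second.span ||
            (span == it->second.span &&
             std::abs(off) < std::abs(it->second.off))) {
          best[pkey] = {span, off, opposite, true};
        }
      }
    }
  }
  std::vector<int> ei, ej, eoff, espan;
  std::vector<std::string> eorient;
  for (auto &kv : best) {
    int i = (int)(kv.first >> 22), j = (int)(kv.first & ((1 << 22) - 1));
    ei.push_back(i + 1); ej.push_back(j + 1);
    eoff.push_back(kv.second.off); espan.push_back(kv.second.span);
    eorient.push_back(kv.second.opposite ? "opposite" : "same");
  }
  return DataFrame::create(_["i"] = ei, _["j"] = ej,
                           _["orientation"] = eorient, _["offset"] = eoff,
                           _["overlap_len"] = espan,
                           _["stringsAsFactors"] = false);
}
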