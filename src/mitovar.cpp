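#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}
static inline char comp_base(char c) {
  switch (c) { case 'A': return 'T'; case 'C': return 'G';
               case 'G': return 'C'; case 'T': return 'A'; default: return 'N'; }
}
static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// ---------------------------------------------------------------------------
// read simulation: fragments on the circle, per-variant haplotype mixing,
// i.i.d. substitution errors. Uses R's RNG so results follow set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_reads(std::string genome, IntegerVector frag_start,
                        IntegerVector frag_len, int read_len,
                        double error_rate, IntegerVector var_pos,
                        CharacterVector var_ref, CharacterVector var_alt,
                        NumericVector var_vaf) {
  const int Lg = genome.size();
  const int n = frag_start.size();
  const int nv = var_pos.size();
  std::vector<std::string> refs(nv), alts(nv);
  for (int v = 0; v < nv; ++v) {
    refs[v] = as<std::string>(var_ref[v]);
    alts[v] = as<std::string>(var_alt[v]);
  }
  CharacterVector r1(n), r2(n);
  const char* bases = "ACGT";
  std::string frag;
  for (int f = 0; f < n; ++f) {
    const int s0 = frag_start[f] - 1;       // 0-based
    const int fl = frag_len[f];
    // variants falling inside this fragment, by fragment offset
    std::vector<std::pair<int, int> > hits;  // (offset, variant idx)
    for (int v = 0; v < nv; ++v) {
      int o = (var_pos[v] - 1) - s0;
      o %= Lg; if (o < 0) o += Lg;
      if (o + (int)refs[v].size() <= fl) hits.push_back(std::make_pair(o, v));
    }
    std::sort(hits.begin(), hits.end());
    frag.clear();
    int cur = 0;
    for (size_t h = 0; h < hits.size(); ++h) {
      const int o = hits[h].first, v = hits[h].second;
      if (o < cur) continue;  // overlapping edit already consumed (shouldn't occur)
      if (unif_rand() >= var_vaf[v]) continue;
      for (int i = cur; i < o; ++i) frag.push_back(genome[(s0 + i) % Lg]);
      frag.append(alts[v]);
      cur = o + refs[v].size();
    }
    for (int i = cur; i < fl; ++i) frag.push_back(genome[(s0 + i) % Lg]);
    std::string a = frag.substr(0, read_len);
    std::string b = revcomp(frag.substr(frag.size() - read_len));
    if (error_rate > 0) {
      for (auto* rd : {&a, &b}) {
        for (auto& c : *rd) {
          if (unif_rand() < error_rate) {
            int cc = base_code(c);
            int pick = (int)(unif_rand() * 3.0); if (pick > 2) pick = 2;
            if (cc < 0) { c = bases[(int)(unif_rand() * 4.0) & 3]; }
            else { c = bases[pick >= cc ? pick + 1 : pick]; }
          }
        }
      }
    }
    r1[f] = a; r2[f] = b;
  }
  return List::create(_["r1"] = r1, _["r2"] = r2);
}

// ---------------------------------------------------------------------------
// k-mer index over the extended (circularized) reference
// ---------------------------------------------------------------------------

struct KIndex {
  int k;
  std::string seq;                       // extended reference
  std::unordered_map<uint64_t, std::vector<int> > map;  // kmer -> 0-based offsets
  int n_offsets;
};

static bool kmer_code(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    code = (code << 2) | (uint64_t)c;
  }
  out = code;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(std::string ext_seq, int k) {
  KIndex* idx = new KIndex();
  idx->k = k;
  idx->seq = ext_seq;
  idx->n_offsets = 0;
  const int n = ext_seq.size();
  uint64_t code;
  for (int p = 0; p + k <= n; ++p) {
    if (kmer_code(ext_seq, p, k, code)) {
      idx->map[code].push_back(p);
      idx->n_offsets++;
    }
  }
  XPtr<KIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_n_offsets(SEXP xp) { return XPtr<KIndex>(xp)->n_offsets; }

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<KIndex> idx(xp);
  uint64_t code;
  if ((int)kmer.size() != idx->k || !kmer_code(kmer, 0, idx->k, code))
    return IntegerVector(0);
  auto it = idx->map.find(code);
  if (it == idx->map.end()) return IntegerVector(0);
  IntegerVector out(it->second.size());
  for (size_t i = 0; i < it->second.size(); ++i) out[i] = it->second[i] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// mapping: seed k-mers, vote on diagonals, ungapped fast path, banded
// affine-gap fitting alignment for reads whose seeds disagree
// ---------------------------------------------------------------------------

struct AlnResult {
  bool mapped = false;
  int start = 0;       // 0-based on extended reference
  bool fwd = true;
  std::string cigar;
  int score = -1000000;
  int nm = 0;
};

struct Scoring {
  int match, mismatch, gap_open, gap_ext, band, min_score;
};

static int hamming_score(const std::string& ref, const std::string& rd,
                         int diag, const Scoring& sc, int& nm, int max_nm) {
  nm = 0;
  const int m = rd.size();
  if (diag < 0 || diag + m > (int)ref.size()) return -1000000;
  for (int i = 0; i < m; ++i) {
    if (ref[diag + i] != rd[i] && ++nm > max_nm) return -1000000;
  }
  return (m - nm) * sc.match + nm * sc.mismatch;
}

// fitting alignment: the read is aligned globally, the reference window
// locally (free leading/trailing reference bases). Affine gaps: a gap of
// length g costs gap_open + g * gap_ext.
static AlnResult banded_fit(const std::string& ref, int w0, int wlen,
                            const std::string& rd, const Scoring& sc) {
  AlnResult res;
  const int m = rd.size();
  if (w0 < 0) { wlen += w0; w0 = 0; }
  if (w0 + wlen > (int)ref.size()) wlen = (int)ref.size() - w0;
  if (wlen < m / 2) return res;
  const int NEG = -100000000;
  const int W = wlen;
  std::vector<int> H((m + 1) * (W + 1), NEG), E((m + 1) * (W + 1), NEG),
      F((m + 1) * (W + 1), NEG);
  std::vector<signed char> TH((m + 1) * (W + 1), 0), TE((m + 1) * (W + 1), 0),
      TF((m + 1) * (W + 1), 0);
  auto at = [W](int i, int j) { return i * (W + 1) + j; };
  for (int j = 0; j <= W; ++j) H[at(0, j)] = 0;  // free ref prefix
  for (int i = 1; i <= m; ++i) {
    E[at(i, 0)] = -(sc.gap_open + i * sc.gap_ext);
    TE[at(i, 0)] = (i >= 2) ? 1 : 0;  // column-0 E cells extend the gap
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= W; ++j) {
      const int sub = (rd[i - 1] == ref[w0 + j - 1] &&
                       base_code(rd[i - 1]) >= 0)
                          ? sc.match : sc.mismatch;
      int hd = H[at(i - 1, j - 1)], ed = E[at(i - 1, j - 1)],
          fd = F[at(i - 1, j - 1)];
      int best = hd; signed char tb = 0;
      if (ed > best) { best = ed; tb = 1; }
      if (fd > best) { best = fd; tb = 2; }
      H[at(i, j)] = best + sub; TH[at(i, j)] = tb;
      // E: gap in reference (insertion in read), consumes read base i
      int eo = H[at(i - 1, j)] - (sc.gap_open + sc.gap_ext);
      int ee = E[at(i - 1, j)] - sc.gap_ext;
      if (eo >= ee) { E[at(i, j)] = eo; TE[at(i, j)] = 0; }
      else { E[at(i, j)] = ee; TE[at(i, j)] = 1; }
      // F: gap in read (deletion of reference), consumes ref base j
      int fo = H[at(i, j - 1)] - (sc.gap_open + sc.gap_ext);
      int fe = F[at(i, j - 1)] - sc.gap_ext;
      if (fo >= fe) { F[at(i, j)] = fo; TF[at(i, j)] = 0; }
      else { F[at(i, j)] = fe; TF[at(i, j)] = 1; }
    }
  }
  int bj = 0, bs = NEG, bm = 0;  // bm: 0 = H, 1 = E
  for (int j = 0; j <= W; ++j) {
    if (H[at(m, j)] > bs) { bs = H[at(m, j)]; bj = j; bm = 0; }
    if (E[at(m, j)] > bs) { bs = E[at(m, j)]; bj = j; bm = 1; }
  }
  if (bs <= NEG / 2) return res;
  // traceback
  std::string ops;
  int i = m, j = bj, state = bm;
  int nm = 0;
  while (i > 0) {
    if (state == 0) {
      signed char tb = TH[at(i, j)];
      ops.push_back('M');
      if (rd[i - 1] != ref[w0 + j - 1]) nm++;
      i--; j--; state = tb;
    } else if (state == 1) {
      signed char tb = TE[at(i, j)];
      ops.push_back('I'); nm++;
      i--; state = (tb == 1) ? 1 : 0;
    } else {
      signed char tb = TF[at(i, j)];
      ops.push_back('D'); nm++;
      j--; state = (tb == 1) ? 2 : 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // strip leading/trailing deletions (free reference) just in case
  size_t b0 = ops.find_first_not_of('D'), b1 = ops.find_last_not_of('D');
  int lead_d = (int)b0;
  ops = ops.substr(b0, b1 - b0 + 1);
  // run-length encode
  std::string cig;
  for (size_t p = 0; p < ops.size();) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cig += std::to_string(q - p); cig.push_back(ops[p]);
    p = q;
  }
  res.mapped = true;
  res.start = w0 + j + lead_d;  // 0-based first aligned reference base
  res.cigar = cig;
  res.score = bs;
  res.nm = nm;
  return res;
}

static void map_one_orientation(const KIndex& idx, const std::string& rd,
                                bool fwd, const Scoring& sc, int seed_step,
                                std::vector<AlnResult>& out) {
  const int m = rd.size();
  const int k = idx.k;
  if (m < k) return;
  std::unordered_map<int, int> votes;  // diagonal -> seed votes
  uint64_t code;
  for (int i = 0; i + k <= m; i += seed_step) {
    if (!kmer_code(rd, i, k, code)) continue;
    auto it = idx.map.find(code);
    if (it == idx.map.end()) continue;
    if (it->second.size() > 64) continue;  // over-represented seed
    for (int p : it->second) votes[p - i]++;
  }
  if (votes.empty()) return;
  // cluster diagonals within the band
  std::vector<std::pair<int, int> > dv(votes.begin(), votes.end());
  std::sort(dv.begin(), dv.end());
  std::vector<std::pair<int, int> > clusters;  // (anchor diag, votes)
  size_t a = 0;
  while (a < dv.size()) {
    size_t b = a; int tot = 0; int best_d = dv[a].first, best_v = -1;
    while (b < dv.size() && dv[b].first - dv[a].first <= sc.band) {
      tot += dv[b].second;
      if (dv[b].second > best_v) { best_v = dv[b].second; best_d = dv[b].first; }
      ++b;
    }
    clusters.push_back(std::make_pair(best_d, tot));
    a = b;
  }
  std::sort(clusters.begin(), clusters.end(),
            [](const std::pair<int,int>& x, const std::pair<int,int>& y) {
              return x.second > y.second; });
  const size_t max_cl = std::min(clusters.size(), (size_t)3);
  for (size_t c = 0; c < max_cl; ++c) {
    const int d = clusters[c].first;
    int nm = 0;
    int hs = hamming_score(idx.seq, rd, d, sc, nm, 5);
    AlnResult r;
    if (hs > -1000000) {
      r.mapped = true; r.start = d; r.cigar = std::to_string(m) + "M";
      r.score = hs; r.nm = nm;
    } else {
      r = banded_fit(idx.seq, d - sc.band, m + 2 * sc.band, rd, sc);
    }
    if (r.mapped) { r.fwd = fwd; out.push_back(r); }
  }
}

// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector seqs, int L, int band,
                   int match, int mismatch, int gap_open, int gap_ext,
                   int min_score, int seed_step) {
  XPtr<KIndex> idx(xp);
  Scoring sc; sc.match = match; sc.mismatch = mismatch;
  sc.gap_open = gap_open; sc.gap_ext = gap_ext; sc.band = band;
  sc.min_score = min_score;
  const int n = seqs.size();
  IntegerVector start(n), score(n), mapq(n), nm(n);
  CharacterVector cigar(n), strand(n);
  LogicalVector mapped(n);
  std::vector<AlnResult> cands;
  for (int r = 0; r < n; ++r) {
    std::string rd = as<std::string>(seqs[r]);
    cands.clear();
    map_one_orientation(*idx, rd, true, sc, seed_step, cands);
    std::string rc = revcomp(rd);
    map_one_orientation(*idx, rc, false, sc, seed_step, cands);
    if (cands.empty()) { mapped[r] = false; continue; }
    // best by score, ties by smallest canonical start
    auto canon = [L](const AlnResult& a) {
      int s = a.start + 1; return s > L ? s - L : s; };
    std::sort(cands.begin(), cands.end(),
              [&](const AlnResult& a, const AlnResult& b) {
                if (a.score != b.score) return a.score > b.score;
                return canon(a) < canon(b); });
    const AlnResult& best = cands[0];
    if (best.score < sc.min_score) { mapped[r] = false; continue; }
    int q = 60;
    for (size_t c = 1; c < cands.size(); ++c) {
      if (cands[c].score >= best.score &&
          (canon(cands[c]) != canon(best) || cands[c].fwd != best.fwd)) {
        q = 0; break;
      }
    }
    mapped[r] = true;
    start[r] = best.start + 1;  // 1-based on extended reference
    strand[r] = best.fwd ? "+" : "-";
    cigar[r] = best.cigar;
    score[r] = best.score;
    mapq[r] = q;
    nm[r] = best.nm;
  }
  return List::create(_["mapped"] = mapped, _["start"] = start,
                      _["strand"] = strand, _["cigar"] = cigar,
                      _["score"] = score, _["mapq"] = mapq, _["nm"] = nm);
}

// ---------------------------------------------------------------------------
// cigar utilities
// ---------------------------------------------------------------------------

static void parse_cigar(const std::string& cig, std::vector<int>& len,
                        std::vector<char>& op) {
  len.clear(); op.clear();
  int v = 0;
  for (char c : cig) {
    if (c >= '0' && c <= '9') v = v * 10 + (c - '0');
    else { len.push_back(v); op.push_back(c); v = 0; }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_cigar_ref_len(CharacterVector cigars) {
  IntegerVector out(cigars.size());
  std::vector<int> len; std::vector<char> op;
  for (int i = 0; i < cigars.size(); ++i) {
    parse_cigar(as<std::string>(cigars[i]), len, op);
    int t = 0;
    for (size_t j = 0; j < op.size(); ++j)
      if (op[j] == 'M' || op[j] == 'D' || op[j] == '=' || op[j] == 'X')
        t += len[j];
    out[i] = t;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_cigar_read_len(CharacterVector cigars) {
  IntegerVector out(cigars.size());
  std::vector<int> len; std::vector<char> op;
  for (int i = 0; i < cigars.size(); ++i) {
    parse_cigar(as<std::string>(cigars[i]), len, op);
    int t = 0;
    for (size_t j = 0; j < op.size(); ++j)
      if (op[j] == 'M' || op[j] == 'I' || op[j] == 'S' || op[j] == '=' ||
          op[j] == 'X')
        t += len[j];
    out[i] = t;
  }
  return out;
}

// ---------------------------------------------------------------------------
// strand-aware pileup
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pileup(int L, IntegerVector start, CharacterVector strand,
                CharacterVector cigar, CharacterVector seq,
                CharacterVector qual, int min_baseq) {
  IntegerVector depth(L), del_span(L);
  IntegerMatrix counts(L, 8);    // A,C,G,T fwd then A,C,G,T rev
  NumericMatrix qualsum(L, 4);
  std::unordered_map<int64_t, std::array<int, 2> > dels;  // anchor*8+dlen
  std::unordered_map<std::string, std::array<int, 2> > inss;
  std::vector<int> len; std::vector<char> op;
  const int n = start.size();
  for (int r = 0; r < n; ++r) {
    parse_cigar(as<std::string>(cigar[r]), len, op);
    const char* s = CHAR(STRING_ELT(seq, r));
    const char* q = CHAR(STRING_ELT(qual, r));
    const bool fwd = (CHAR(STRING_ELT(strand, r))[0] == '+');
    int rpos = start[r] - 1;  // 0-based
    int qpos = 0;
    if (rpos < 0) stop("alignment start below 1");
    for (size_t j = 0; j < op.size(); ++j) {
      const int l = len[j];
      switch (op[j]) {
      case 'M': case '=': case 'X':
        if (rpos + l > L) stop("alignment extends beyond reference end");
        for (int t = 0; t < l; ++t) {
          depth[rpos]++;
          const int bq = q[qpos] - 33;
          const int c = base_code(s[qpos]);
          if (c >= 0 && bq >= min_baseq) {
            counts(rpos, c + (fwd ? 0 : 4))++;
            qualsum(rpos, c) += bq;
          }
          rpos++; qpos++;
        }
        break;
      case 'I': {
        if (rpos >= 1 && rpos <= L) {
          std::string key = std::to_string(rpos) + ":" +
                            std::string(s + qpos, l);
          inss[key][fwd ? 0 : 1]++;
        }
        qpos += l;
        break;
      }
      case 'D': {
        if (rpos + l > L) stop("alignment extends beyond reference end");
        if (rpos >= 1) dels[(int64_t)rpos * 1024 + l][fwd ? 0 : 1]++;
        for (int t = 0; t < l; ++t) { depth[rpos]++; del_span[rpos]++; rpos++; }
        break;
      }
      case 'S': case 'H':
        if (op[j] == 'S') qpos += l;
        break;
      default:
        stop("unsupported cigar op");
      }
    }
  }
  // flatten indel maps
  int nd = dels.size();
  IntegerVector d_anchor(nd), d_len(nd), d_fwd(nd), d_rev(nd);
  int i = 0;
  for (auto& kv : dels) {
    d_anchor[i] = kv.first / 1024; d_len[i] = kv.first % 1024;
    d_fwd[i] = kv.second[0]; d_rev[i] = kv.second[1]; ++i;
  }
  int ni = inss.size();
  IntegerVector i_anchor(ni), i_fwd(ni), i_rev(ni);
  CharacterVector i_seq(ni);
  i = 0;
  for (auto& kv : inss) {
    size_t colon = kv.first.find(':');
    int a = 0;
    for (size_t t = 0; t < colon; ++t) a = a * 10 + (kv.first[t] - '0');
    i_anchor[i] = a;
    i_seq[i] = kv.first.substr(colon + 1);
    i_fwd[i] = kv.second[0]; i_rev[i] = kv.second[1]; ++i;
  }
  return List::create(
      _["depth"] = depth, _["counts"] = counts, _["qualsum"] = qualsum,
      _["del_span"] = del_span,
      _["dels"] = DataFrame::create(_["anchor"] = d_anchor, _["dlen"] = d_len,
                                    _["fwd"] = d_fwd, _["rev"] = d_rev),
      _["inss"] = DataFrame::create(_["anchor"] = i_anchor, _["seq"] = i_seq,
                                    _["fwd"] = i_fwd, _["rev"] = i_rev,
                                    _["stringsAsFactors"] = false));
}

// ---------------------------------------------------------------------------
// small string helpers used on large read tables
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_reverse_strings(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::reverse(s.begin(), s.end());
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_qual_sums(CharacterVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    double t = 0;
    for (; *s; ++s) t += *s - 33;
    out[i] = t;
  }
  return out;
}
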