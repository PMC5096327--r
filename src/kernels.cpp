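#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Residue codes are 0-based; codes >= asize (the indexable alphabet size) are
// masked and never form an indexed word. Word ids are base-asize numerals.

static inline int word_at(const int* s, int pos, int W, int asize) {
  int id = 0;
  for (int k = 0; k < W; ++k) {
    int c = s[pos + k];
    if (c < 0 || c >= asize) return -1;
    id = id * asize + c;
  }
  return id;
}

static int n_words_for(int asize, int W) {
  double n = 1;
  for (int k = 0; k < W; ++k) n *= asize;
  if (n > 2147483000.0) stop("alphabet^W too large");
  return (int)n;
}

// ---------------------------------------------------------------- basic index

// [[Rcpp::export(name = ".basic_index_cpp")]]
List basic_index_cpp(List seqs, int W, int asize) {
  int n_words = n_words_for(asize, W);
  int n_seq = seqs.size();
  std::vector<int> cnt(n_words + 1, 0);
  for (int s = 0; s < n_seq; ++s) {
    IntegerVector sq = seqs[s];
    int L = sq.size();
    for (int p = 0; p + W <= L; ++p) {
      int w = word_at(sq.begin(), p, W, asize);
      if (w >= 0) cnt[w + 1]++;
    }
  }
  IntegerVector word_start(n_words + 1);
  for (int w = 1; w <= n_words; ++w) cnt[w] += cnt[w - 1];
  for (int w = 0; w <= n_words; ++w) word_start[w] = cnt[w];
  int total = cnt[n_words];
  IntegerVector seq_id(total), offset(total);
  std::vector<int> fill(n_words);
  for (int w = 0; w < n_words; ++w) fill[w] = word_start[w];
  for (int s = 0; s < n_seq; ++s) {
    IntegerVector sq = seqs[s];
    int L = sq.size();
    for (int p = 0; p + W <= L; ++p) {
      int w = word_at(sq.begin(), p, W, asize);
      if (w >= 0) { int k = fill[w]++; seq_id[k] = s; offset[k] = p; }
    }
  }
  return List::create(_["word_start"] = word_start,
                      _["seq_id"] = seq_id, _["offset"] = offset);
}

// [[Rcpp::export(name = ".sort_index_cpp")]]
List sort_index_cpp(IntegerVector word_start, IntegerVector seq_id,
                    IntegerVector offset) {
  int n_words = word_start.size() - 1;
  int total = seq_id.size();
  IntegerVector out_seq(total), out_off(total);
  std::vector<int> idx;
  for (int w = 0; w < n_words; ++w) {
    int a = word_start[w], b = word_start[w + 1];
    if (a == b) continue;
    idx.resize(b - a);
    for (int i = a; i < b; ++i) idx[i - a] = i;
    std::stable_sort(idx.begin(), idx.end(), [&](int i, int j) {
      if (offset[i] != offset[j]) return offset[i] < offset[j];
      return seq_id[i] < seq_id[j];
    });
    for (int i = a; i < b; ++i) {
      out_seq[i] = seq_id[idx[i - a]];
      out_off[i] = offset[idx[i - a]];
    }
  }
  return List::create(_["word_start"] = word_start,
                      _["seq_id"] = out_seq, _["offset"] = out_off);
}

// Whole-block merge + increment compression of a sorted position array.
// Per word: runs of equal subject offset merge into one entry (offset stored
// once, all seq ids); offsets become 8-bit increments from the previous
// entry's absolute offset (first entry from 0); increments > 255 emit
// (255, 0, []) padding entries, counts > 255 emit maximal 255-count entries
// first. Mirrors the R-level compress_positions()/split_overflow().
// [[Rcpp::export(name = ".compress_block_cpp")]]
List compress_block_cpp(IntegerVector word_start, IntegerVector seq_id,
                        IntegerVector offset) {
  int n_words = word_start.size() - 1;
  std::vector<int> es(n_words + 1, 0), dl, ct, sd;
  dl.reserve(seq_id.size()); ct.reserve(seq_id.size());
  sd.reserve(seq_id.size());
  for (int w = 0; w < n_words; ++w) {
    int a = word_start[w], b = word_start[w + 1];
    int prev_abs = 0;
    int i = a;
    while (i < b) {
      int off = offset[i];
      int j = i;
      while (j < b && offset[j] == off) ++j;  // run sharing this offset
      int delta = off - prev_abs;
      while (delta > 255) { dl.push_back(255); ct.push_back(0); delta -= 255; }
      int n_ids = j - i, taken = 0;
      bool first = true;
      while (taken < n_ids) {
        int take = std::min(n_ids - taken, 255);
        dl.push_back(first ? delta : 0);
        ct.push_back(take);
        for (int k = 0; k < take; ++k) sd.push_back(seq_id[i + taken + k]);
        taken += take;
        first = false;
      }
      prev_abs = off;
      i = j;
    }
    es[w + 1] = (int)dl.size();
  }
  IntegerVector sid_start(ct.size() + 1);
  long acc = 0;
  sid_start[0] = 0;
  for (size_t e = 0; e < ct.size(); ++e) { acc += ct[e]; sid_start[e + 1] = (int)acc; }
  return List::create(
    _["entry_start"] = IntegerVector(es.begin(), es.end()),
    _["delta"] = IntegerVector(dl.begin(), dl.end()),
    _["count"] = IntegerVector(ct.begin(), ct.end()),
    _["sid_start"] = sid_start,
    _["sids"] = IntegerVector(sd.begin(), sd.end()));
}

// ------------------------------------------------------------- neighbor words

// All words v != w with sum_k S[w_k, v_k] >= T, ascending v, for every w.
// [[Rcpp::export(name = ".neighbors_all_cpp")]]
List neighbors_all_cpp(IntegerMatrix S, double T, int W, int asize) {
  int n_words = n_words_for(asize, W);
  std::vector<std::vector<int>> codes(n_words, std::vector<int>(W));
  for (int w = 0; w < n_words; ++w) {
    int x = w;
    for (int k = W - 1; k >= 0; --k) { codes[w][k] = x % asize; x /= asize; }
  }
  std::vector<int> nb;
  IntegerVector nb_start(n_words + 1);
  nb.reserve(n_words * 8);
  for (int w = 0; w < n_words; ++w) {
    nb_start[w] = (int)nb.size();
    const std::vector<int>& cw = codes[w];
    // per-position score rows for this word
    for (int v = 0; v < n_words; ++v) {
      if (v == w) continue;
      int sc = 0, x = v;
      for (int k = W - 1; k >= 0; --k) { sc += S(cw[k], x % asize); x /= asize; }
      if (sc >= T) nb.push_back(v);
    }
  }
  nb_start[n_words] = (int)nb.size();
  return List::create(_["nb_start"] = nb_start,
                      _["nb"] = IntegerVector(nb.begin(), nb.end()));
}

// -------------------------------------------------- hit detection and binning

// Decode one word's compressed posting run, appending hits for query position p.
// cb(abs_offset, seq_id) called for each decoded position, in stored order.
template <typename F>
static inline void decode_word(int w, const int* entry_start, const int* delta,
                               const int* cnt, const int* sid_start,
                               const int* sids, F cb) {
  int abs_off = 0;
  for (int e = entry_start[w]; e < entry_start[w + 1]; ++e) {
    abs_off += delta[e];
    int c = cnt[e];
    int s0 = sid_start[e];
    for (int k = 0; k < c; ++k) cb(abs_off, sids[s0 + k]);
  }
}

// First-level binning straight off the compressed index: for each query
// position p, the posting runs of the exact word and of each neighbor are
// decoded and every position (seq, off) becomes a hit in bin off - p.
// Bins are indexed off - p + qlen - 1 (dense, non-negative).
// [[Rcpp::export(name = ".detect_hits_cpp")]]
List detect_hits_cpp(IntegerVector qcodes, IntegerVector entry_start,
                     IntegerVector delta, IntegerVector cnt,
                     IntegerVector sid_start, IntegerVector sids,
                     IntegerVector nb_start, IntegerVector nb,
                     int W, int asize, int max_len) {
  int qlen = qcodes.size();
  int n_bins = qlen + max_len;  // diag in [-(qlen-1), max_len-1]
  std::vector<int> bin_cnt(n_bins + 1, 0);
  const int* es = entry_start.begin();
  const int* de = delta.begin();
  const int* ct = cnt.begin();
  const int* ss = sid_start.begin();
  const int* si = sids.begin();

  auto for_each_hit = [&](auto cb) {
    for (int p = 0; p + W <= qlen; ++p) {
      int w = word_at(qcodes.begin(), p, W, asize);
      if (w < 0) continue;
      decode_word(w, es, de, ct, ss, si,
                  [&](int off, int sid) { cb(p, off, sid); });
      for (int t = nb_start[w]; t < nb_start[w + 1]; ++t) {
        decode_word(nb[t], es, de, ct, ss, si,
                    [&](int off, int sid) { cb(p, off, sid); });
      }
    }
  };

  for_each_hit([&](int p, int off, int sid) {
    (void)sid; bin_cnt[off - p + qlen - 1 + 1]++;
  });
  for (int b = 1; b <= n_bins; ++b) bin_cnt[b] += bin_cnt[b - 1];
  IntegerVector bin_start(n_bins + 1);
  for (int b = 0; b <= n_bins; ++b) bin_start[b] = bin_cnt[b];
  int total = bin_cnt[n_bins];
  IntegerVector h_seq(total), h_off(total);
  std::vector<int> fill(n_bins);
  for (int b = 0; b < n_bins; ++b) fill[b] = bin_start[b];
  for_each_hit([&](int p, int off, int sid) {
    int k = fill[off - p + qlen - 1]++;
    h_seq[k] = sid; h_off[k] = off;
  });
  return List::create(_["bin_start"] = bin_start, _["seq_id"] = h_seq,
                      _["subject_offset"] = h_off, _["qlen"] = qlen);
}

// Two-hit filter over first-level bins scanned in ascending diagonal order.
// A last-hit array keyed by sequence id stores (diagonal, subject offset) of
// the most recent hit; a hit whose distance to the last hit on the same
// diagonal lies in [overlap, window) is emitted into the second-level bin of
// its sequence. The last-hit record is always updated.
// [[Rcpp::export(name = ".filter_pairs_cpp")]]
List filter_pairs_cpp(IntegerVector h_diag, IntegerVector h_seq,
                      IntegerVector h_off, int n_seqs,
                      int window, int overlap) {
  int n = h_diag.size();
  std::vector<int> last_diag(n_seqs, INT_MIN), last_off(n_seqs, 0);
  std::vector<int> em_seq, em_off, em_diag;
  for (int i = 0; i < n; ++i) {
    int diag = h_diag[i], s = h_seq[i], off = h_off[i];
    if (last_diag[s] == diag) {
      int d = off - last_off[s];
      if (d >= overlap && d < window) {
        em_seq.push_back(s); em_off.push_back(off); em_diag.push_back(diag);
      }
    }
    last_diag[s] = diag; last_off[s] = off;
  }
  // scatter into second-level (per-sequence) bins, stable in scan order
  int m = (int)em_seq.size();
  IntegerVector bin2_start(n_seqs + 1);
  std::vector<int> c2(n_seqs + 1, 0);
  for (int i = 0; i < m; ++i) c2[em_seq[i] + 1]++;
  for (int s = 1; s <= n_seqs; ++s) c2[s] += c2[s - 1];
  for (int s = 0; s <= n_seqs; ++s) bin2_start[s] = c2[s];
  IntegerVector o_seq(m), o_off(m), o_diag(m);
  std::vector<int> fill(n_seqs);
  for (int s = 0; s < n_seqs; ++s) fill[s] = bin2_start[s];
  for (int i = 0; i < m; ++i) {
    int k = fill[em_seq[i]]++;
    o_seq[k] = em_seq[i]; o_off[k] = em_off[i]; o_diag[k] = em_diag[i];
  }
  return List::create(_["bin2_start"] = bin2_start, _["seq_id"] = o_seq,
                      _["subject_offset"] = o_off, _["diagonal"] = o_diag);
}

// --------------------------------------------------------- ungapped extension

// X-drop ungapped extension along the diagonal from the seeded word.
// Returns {q_start, q_end, s_start, s_end, score} (0-based, half-open), or
// score < cutoff results are still returned (caller filters) so that the
// diagonal gating state is identical across callers.
static void ungapped_one(const int* q, int qlen, const int* s, int slen,
                         int q_pos, int s_pos, int W,
                         const int* S, int asize_full, int xdrop, int out[5]) {
  int word = 0;
  for (int k = 0; k < W; ++k) word += S[q[q_pos + k] * asize_full + s[s_pos + k]];
  // left of the word
  int best_l = 0, run = 0, ext_l = 0;
  for (int i = q_pos - 1, j = s_pos - 1, k = 1; i >= 0 && j >= 0; --i, --j, ++k) {
    run += S[q[i] * asize_full + s[j]];
    if (run > best_l) { best_l = run; ext_l = k; }
    else if (best_l - run > xdrop) break;
  }
  // right of the word
  int best_r = 0, ext_r = 0;
  run = 0;
  for (int i = q_pos + W, j = s_pos + W, k = 1; i < qlen && j < slen; ++i, ++j, ++k) {
    run += S[q[i] * asize_full + s[j]];
    if (run > best_r) { best_r = run; ext_r = k; }
    else if (best_r - run > xdrop) break;
  }
  out[0] = q_pos - ext_l; out[1] = q_pos + W + ext_r;
  out[2] = s_pos - ext_l; out[3] = s_pos + W + ext_r;
  out[4] = word + best_l + best_r;
}

// [[Rcpp::export(name = ".ungapped_one_cpp")]]
IntegerVector ungapped_one_cpp(IntegerVector q, IntegerVector s, int q_pos,
                               int s_pos, int W, IntegerMatrix S, int xdrop) {
  if (q_pos < 0 || s_pos < 0 || q_pos + W > q.size() || s_pos + W > s.size())
    stop("seed word out of sequence bounds");
  int out[5];
  ungapped_one(q.begin(), q.size(), s.begin(), s.size(), q_pos, s_pos, W,
               S.begin(), S.nrow(), xdrop, out);
  return IntegerVector(out, out + 5);
}

// Batch two-hit extension over second-level bins. Hits within one sequence
// bin arrive ordered by (diagonal, subject offset); per diagonal, a seed whose
// offset does not pass the right end of the previous extension on that
// diagonal is skipped (diagonal-local, order-independent gating).
// [[Rcpp::export(name = ".ungapped_block_cpp")]]
IntegerMatrix ungapped_block_cpp(IntegerVector qcodes, List seqs,
                                 IntegerVector bin2_start, IntegerVector p_off,
                                 IntegerVector p_diag, int W, IntegerMatrix S,
                                 int xdrop, int cutoff) {
  int n_seqs = bin2_start.size() - 1;
  const int* q = qcodes.begin();
  int qlen = qcodes.size();
  std::vector<int> rows;
  for (int s = 0; s < n_seqs; ++s) {
    int a = bin2_start[s], b = bin2_start[s + 1];
    if (a == b) continue;
    IntegerVector sq = seqs[s];
    const int* sub = sq.begin();
    int slen = sq.size();
    int cur_diag = INT_MIN, last_end = INT_MIN;
    for (int i = a; i < b; ++i) {
      int diag = p_diag[i], off = p_off[i];
      if (diag != cur_diag) { cur_diag = diag; last_end = INT_MIN; }
      if (off <= last_end) continue;
      int q_pos = off - diag;
      int out[5];
      ungapped_one(q, qlen, sub, slen, q_pos, off, W, S.begin(), S.nrow(),
                   xdrop, out);
      last_end = out[3] - 1;
      if (out[4] >= cutoff) {
        rows.push_back(s);
        for (int k = 0; k < 5; ++k) rows.push_back(out[k]);
      }
    }
  }
  int n = (int)rows.size() / 6;
  IntegerMatrix res(n, 6);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 6; ++k) res(i, k) = rows[i * 6 + k];
  colnames(res) = CharacterVector::create("seq_id", "q_start", "q_end",
                                          "s_start", "s_end", "score");
  return res;
}

// ----------------------------------------------------------- gapped extension

// One half of a gapped X-drop extension: global-from-origin affine DP over
// q[0..qn) x s[0..sn), pruned to cells with H >= best - xdrop. A gap of
// length L costs gap_open + gap_extend * L. Returns best score, end cell of
// the best prefix, and edit ops (M/I/D; I consumes query only) from origin
// to that cell.
struct HalfExt { int score, qi, sj; std::string ops; };

static HalfExt xdrop_half(const int* q, int qn, const int* s, int sn,
                          const int* S, int asize_full,
                          int go, int ge, long xdrop) {
  const long NEG = LONG_MIN / 4;
  long goe = (long)go + ge;  // cost of a length-1 gap
  // traceback bytes: bit0-1 H source (0 diag, 1 E, 2 F), bit2 E ext, bit3 F ext
  std::vector<unsigned char> tb((size_t)(qn + 1) * (sn + 1), 0);
  std::vector<long> Hprev(sn + 1, NEG), Eprev(sn + 1, NEG), Fprev(sn + 1, NEG);
  std::vector<long> Hcur(sn + 1, NEG), Ecur(sn + 1, NEG), Fcur(sn + 1, NEG);
  long best = 0; int best_i = 0, best_j = 0;
  int lo = 0, hi = 0;  // live column range of the previous row
  Hprev[0] = 0;
  for (int j = 1; j <= sn; ++j) {
    long v = -(goe + (long)ge * (j - 1));
    if (best - v > xdrop) break;
    Eprev[j] = v; Hprev[j] = v;
    tb[j] = (unsigned char)(1 | (j > 1 ? 4 : 0));
    hi = j;
  }
  for (int i = 1; i <= qn; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    int new_lo = -1, new_hi = -1;
    int jstart = lo;
    if (jstart == 0) {
      long v = -(goe + (long)ge * (i - 1));
      if (best - v <= xdrop) {
        Hcur[0] = Fcur[0] = v;
        tb[(size_t)i * (sn + 1)] = (unsigned char)(2 | (i > 1 ? 8 : 0));
        new_lo = 0; new_hi = 0;
      }
      jstart = 1;
    }
    for (int j = jstart; j <= sn; ++j) {
      // E: gap consuming subject, from the left in the current row
      long e_open = (Hcur[j - 1] == NEG) ? NEG : Hcur[j - 1] - goe;
      long e_ext  = (Ecur[j - 1] == NEG) ? NEG : Ecur[j - 1] - ge;
      long e; unsigned char eb;
      if (e_ext > e_open) { e = e_ext; eb = 4; } else { e = e_open; eb = 0; }
      // F: gap consuming query, from the previous row, same column
      long f_open = (Hprev[j] == NEG) ? NEG : Hprev[j] - goe;
      long f_ext  = (Fprev[j] == NEG) ? NEG : Fprev[j] - ge;
      long f; unsigned char fb;
      if (f_ext > f_open) { f = f_ext; fb = 8; } else { f = f_open; fb = 0; }
      long dg = (Hprev[j - 1] == NEG)
                  ? NEG : Hprev[j - 1] + S[q[i - 1] * asize_full + s[j - 1]];
      long h = dg; unsigned char hb = 0;
      if (e > h) { h = e; hb = 1; }
      if (f > h) { h = f; hb = 2; }
      if (h <= NEG / 2 || best - h > xdrop) {
        // dead cell; beyond the previous row's band only E can feed the row,
        // and E only decays rightward, so the row is finished
        if (j > hi + 1) break;
        continue;
      }
      Hcur[j] = h; Ecur[j] = e; Fcur[j] = f;
      tb[(size_t)i * (sn + 1) + j] = (unsigned char)(hb | eb | fb);
      if (h > best) { best = h; best_i = i; best_j = j; }
      if (new_lo < 0) new_lo = j;
      new_hi = j;
    }
    if (new_lo < 0) break;  // no live cell: extension finished
    lo = new_lo; hi = new_hi;
    Hprev.swap(Hcur); Eprev.swap(Ecur); Fprev.swap(Fcur);
  }
  // traceback from (best_i, best_j) to (0,0)
  std::string ops;
  int i = best_i, j = best_j;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    unsigned char b = tb[(size_t)i * (sn + 1) + j];
    if (state == 0) state = b & 3;
    if (state == 0) { ops.push_back('M'); --i; --j; }
    else if (state == 1) { ops.push_back('D'); state = (b & 4) ? 1 : 0; --j;
      if (state == 1) { /* stay in E for previous column */ }
    }
    else { ops.push_back('I'); state = (b & 8) ? 2 : 0; --i; }
  }
  std::reverse(ops.begin(), ops.end());
  HalfExt r; r.score = (int)best; r.qi = best_i; r.sj = best_j; r.ops = ops;
  return r;
}

// [[Rcpp::export(name = ".gapped_extend_cpp")]]
List gapped_extend_cpp(IntegerVector qcodes, IntegerVector scodes,
                       int q_seed, int s_seed, IntegerMatrix S,
                       int gap_open, int gap_extend, double xdrop) {
  int qlen = qcodes.size(), slen = scodes.size();
  if (q_seed < 0 || s_seed < 0 || q_seed >= qlen || s_seed >= slen)
    stop("seed out of bounds");
  long xd = (xdrop >= 1e17) ? (LONG_MAX / 8) : (long)xdrop;
  // left half on reversed prefixes (excluding the seed cell)
  std::vector<int> qr(q_seed), sr(s_seed);
  for (int i = 0; i < q_seed; ++i) qr[i] = qcodes[q_seed - 1 - i];
  for (int j = 0; j < s_seed; ++j) sr[j] = scodes[s_seed - 1 - j];
  HalfExt L = xdrop_half(qr.data(), q_seed, sr.data(), s_seed,
                         S.begin(), S.nrow(), gap_open, gap_extend, xd);
  // right half includes the seed cell
  HalfExt R = xdrop_half(qcodes.begin() + q_seed, qlen - q_seed,
                         scodes.begin() + s_seed, slen - s_seed,
                         S.begin(), S.nrow(), gap_open, gap_extend, xd);
  std::string ops(L.ops.rbegin(), L.ops.rend());
  ops += R.ops;
  int q_start = q_seed - L.qi, s_start = s_seed - L.sj;
  int q_end = q_seed + R.qi, s_end = s_seed + R.sj;
  // alignment statistics from the edit string
  int iq = q_start, js = s_start, ident = 0, posit = 0, gaps = 0;
  for (char c : ops) {
    if (c == 'M') {
      int a = qcodes[iq], b = scodes[js];
      if (a == b) ident++;
      if (S(a, b) > 0) posit++;
      iq++; js++;
    } else if (c == 'I') { iq++; gaps++; }
    else { js++; gaps++; }
  }
  return List::create(_["score"] = L.score + R.score,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["s_start"] = s_start, _["s_end"] = s_end,
                      _["ops"] = ops, _["identities"] = ident,
                      _["positives"] = posit, _["gaps"] = gaps,
                      _["length"] = (int)ops.size());
}
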