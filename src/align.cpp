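#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Seed-and-extend chimera aligner.
//
// Candidate (read, reference) pairs are selected by exact k-mer anchoring
// (default k = 12); each candidate pair is then resolved with a local
// Gotoh alignment (match +1, mismatch -1, gap open -6, gap extend -1, so a
// 1-nt gap costs 7 -- the Biostrings::pairwiseAlignment convention).  One
// best local alignment per (read, reference) pair is reported, with CIGAR
// and MD strings so downstream mutation calling works from standard tags.

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

struct AlnRes {
  bool ok;
  int score, rd_s, rd_e, rf_s, rf_e, nmm;
  std::string cigar, md;
};

static AlnRes gotoh_local(const std::string& rd, const std::string& rf,
                          int mat, int mis, int go, int ge) {
  AlnRes res;
  res.ok = false;
  const int n = (int) rd.size(), m = (int) rf.size();
  if (n == 0 || m == 0) return res;
  const int NEG = -1000000;
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG), F((n + 1) * W, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; i++) {
    for (int j = 1; j <= m; j++) {
      const int idx = i * W + j;
      const int eo = H[i * W + j - 1] - (go + ge);
      const int ee = E[i * W + j - 1] - ge;
      E[idx] = eo > ee ? eo : ee;
      const int fo = H[(i - 1) * W + j] - (go + ge);
      const int fe = F[(i - 1) * W + j] - ge;
      F[idx] = fo > fe ? fo : fe;
      const int s = (rd[i - 1] == rf[j - 1] && rd[i - 1] != 'N') ? mat : mis;
      int h = H[(i - 1) * W + j - 1] + s;
      if (E[idx] > h) h = E[idx];
      if (F[idx] > h) h = F[idx];
      if (h < 0) h = 0;
      H[idx] = h;
      // first maximum in scan order -> deterministic (smallest read end,
      // then smallest ref end)
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return res;

  // traceback: prefer diagonal, then gap-in-read (D), then gap-in-ref (I);
  // within a gap state prefer closing the gap (shortest gap consistent with
  // the score)
  std::string ops;  // reversed op per alignment column
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    const int idx = i * W + j;
    if (state == 'H') {
      if (H[idx] == 0) break;
      const int s = (rd[i - 1] == rf[j - 1] && rd[i - 1] != 'N') ? mat : mis;
      if (H[idx] == H[(i - 1) * W + j - 1] + s) {
        ops.push_back('M'); i--; j--;
      } else if (H[idx] == E[idx]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      const bool open = (E[idx] == H[i * W + j - 1] - (go + ge));
      ops.push_back('D');
      j--;
      if (open) state = 'H';
    } else {
      const bool open = (F[idx] == H[(i - 1) * W + j] - (go + ge));
      ops.push_back('I');
      i--;
      if (open) state = 'H';
    }
  }

  res.rd_s = i + 1; res.rf_s = j + 1;
  res.rd_e = bi;    res.rf_e = bj;
  res.score = best;

  // walk the alignment forward to build CIGAR, MD and the mismatch count
  std::string cigar, md;
  int run = 0, nmm = 0;
  int ri = i, rj = j;  // 0-based indices of next bases
  char cur_op = 0;
  int cur_len = 0;
  bool in_del = false;
  for (int p = (int) ops.size() - 1; p >= 0; p--) {
    const char op = ops[p];
    if (op != cur_op) {
      if (cur_len > 0) { cigar += std::to_string(cur_len); cigar.push_back(cur_op); }
      cur_op = op; cur_len = 0;
    }
    cur_len++;
    if (op == 'M') {
      if (in_del) { in_del = false; }
      if (rd[ri] == rf[rj] && rd[ri] != 'N') {
        run++;
      } else {
        md += std::to_string(run);
        md.push_back(rf[rj]);
        run = 0;
        nmm++;
      }
      ri++; rj++;
    } else if (op == 'D') {
      if (!in_del) {
        md += std::to_string(run);
        run = 0;
        md.push_back('^');
        in_del = true;
      }
      md.push_back(rf[rj]);
      rj++;
    } else {  // I
      in_del = false;
      ri++;
    }
  }
  if (cur_len > 0) { cigar += std::to_string(cur_len); cigar.push_back(cur_op); }
  md += std::to_string(run);

  res.cigar = cigar;
  res.md = md;
  res.nmm = nmm;
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_align_segments(CharacterVector read_id, CharacterVector read_seq,
                        CharacterVector ref_id, CharacterVector ref_seq,
                        IntegerVector ref_min_len, int k, int max_mismatch,
                        int match, int mismatch, int gap_open, int gap_ext) {
  const int nref = ref_seq.size();
  const int nread = read_seq.size();
  const uint32_t mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);

  // k-mer -> reference indices (each reference listed once per k-mer)
  std::unordered_map<uint32_t, std::vector<int> > index;
  index.reserve(4096);
  std::vector<std::string> refs(nref);
  for (int r = 0; r < nref; r++) {
    refs[r] = as<std::string>(ref_seq[r]);
    const std::string& s = refs[r];
    uint32_t val = 0;
    int valid = 0;
    for (size_t p = 0; p < s.size(); p++) {
      const int b = base2bit(s[p]);
      if (b < 0) { valid = 0; val = 0; continue; }
      val = ((val << 2) | (uint32_t) b) & mask;
      valid++;
      if (valid >= k) {
        std::vector<int>& v = index[val];
        if (v.empty() || v.back() != r) v.push_back(r);
      }
    }
  }

  std::vector<std::string> out_read, out_ref, out_cigar, out_md;
  std::vector<int> out_rds, out_rde, out_rfs, out_rfe, out_nmm, out_score;
  std::vector<char> seen(nref, 0);
  std::vector<int> cands;

  for (int q = 0; q < nread; q++) {
    const std::string rd = as<std::string>(read_seq[q]);
    if ((int) rd.size() < k) continue;
    cands.clear();
    uint32_t val = 0;
    int valid = 0;
    for (size_t p = 0; p < rd.size(); p++) {
      const int b = base2bit(rd[p]);
      if (b < 0) { valid = 0; val = 0; continue; }
      val = ((val << 2) | (uint32_t) b) & mask;
      valid++;
      if (valid >= k) {
        std::unordered_map<uint32_t, std::vector<int> >::const_iterator it =
          index.find(val);
        if (it != index.end()) {
          for (size_t z = 0; z < it->second.size(); z++) {
            const int r = it->second[z];
            if (!seen[r]) { seen[r] = 1; cands.push_back(r); }
          }
        }
      }
    }
    for (size_t z = 0; z < cands.size(); z++) {
      const int r = cands[z];
      seen[r] = 0;
      AlnRes a = gotoh_local(rd, refs[r], match, mismatch, gap_open, gap_ext);
      if (!a.ok) continue;
      if (a.nmm > max_mismatch) continue;
      if (a.rd_e - a.rd_s + 1 < ref_min_len[r]) continue;
      out_read.push_back(as<std::string>(read_id[q]));
      out_ref.push_back(as<std::string>(ref_id[r]));
      out_rds.push_back(a.rd_s);
      out_rde.push_back(a.rd_e);
      out_rfs.push_back(a.rf_s);
      out_rfe.push_back(a.rf_e);
      out_cigar.push_back(a.cigar);
      out_md.push_back(a.md);
      out_nmm.push_back(a.nmm);
      out_score.push_back(a.score);
    }
  }

  return List::create(
    _["read_id"] = wrap(out_read), _["ref_id"] = wrap(out_ref),
    _["read_start"] = wrap(out_rds), _["read_end"] = wrap(out_rde),
    _["ref_start"] = wrap(out_rfs), _["ref_end"] = wrap(out_rfe),
    _["cigar"] = wrap(out_cigar), _["md"] = wrap(out_md),
    _["n_mismatch"] = wrap(out_nmm), _["score"] = wrap(out_score));
}

// [[Rcpp::export]]
List cpp_align_pair(std::string read, std::string ref, int match, int mismatch,
                    int gap_open, int gap_ext) {
  AlnRes a = gotoh_local(read, ref, match, mismatch, gap_open, gap_ext);
  if (!a.ok) return List::create(_["ok"] = false);
  return List::create(
    _["ok"] = true, _["score"] = a.score,
    _["read_start"] = a.rd_s, _["read_end"] = a.rd_e,
    _["ref_start"] = a.rf_s, _["ref_end"] = a.rf_e,
    _["cigar"] = a.cigar, _["md"] = a.md, _["n_mismatch"] = a.nmm);
}
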