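// Alignment engines shared by the read mapper and the assembly scanner.
//
// Conventions: all coordinates 0-based half-open; a gap of length g scores
// gap_open + g * gap_ext (both negative), i.e. the opening penalty is charged
// once per gap on top of a per-column extension penalty.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N (or anything else) never matches
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': case 'a': c = 'T'; break;
      case 'C': case 'c': c = 'G'; break;
      case 'G': case 'g': c = 'C'; break;
      case 'T': case 't': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// traceback byte layout: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F),
// bit 2: E extends E, bit 3: F extends F
struct SWResult {
  int score, q_start, q_end, t_start, t_end;
  int matches, mismatches, gap_cols;
  std::string cigar;
};

// local_query = true: classic Smith-Waterman (both sequences local).
// local_query = false: glocal - the whole query must align (terminal query
// bases are kept as mismatches or gaps, never clipped) while the target
// stays local; used by the read mapper so that pileup columns at read ends
// keep their minor alleles.
static SWResult sw_core(const std::string &query, const std::string &target,
                        int match, int mismatch, int gap_open, int gap_ext,
                        bool local_query = true) {
  const int n = (int) query.size(), m = (int) target.size();
  if ((double) n * (double) m > 6e8)
    stop("alignment problem too large (%d x %d)", n, m);
  std::vector<int> qc(n), tc(m);
  for (int i = 0; i < n; ++i) qc[i] = base_code(query[i]);
  for (int j = 0; j < m; ++j) tc[j] = base_code(target[j]);

  const int NEG = INT32_MIN / 4;
  std::vector<uint8_t> tb((size_t) n * m, 0);
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fcol(m + 1, NEG);
  int best = local_query ? 0 : NEG, bi = -1, bj = -1;
  const int open_cost = gap_open + gap_ext;

  for (int i = 1; i <= n; ++i) {
    int E = NEG;
    Hcur[0] = local_query ? 0 : open_cost + (i - 1) * gap_ext;
    for (int j = 1; j <= m; ++j) {
      uint8_t t = 0;
      int e_open = Hcur[j - 1] + open_cost;
      int e_ext = E + gap_ext;
      if (e_ext > e_open) { E = e_ext; t |= 4; } else E = e_open;
      int f_open = Hprev[j] + open_cost;
      int f_ext = Fcol[j] + gap_ext;
      int F;
      if (f_ext > f_open) { F = f_ext; t |= 8; } else F = f_open;
      Fcol[j] = F;
      int s = (qc[i - 1] == tc[j - 1] && qc[i - 1] < 4) ? match : mismatch;
      int diag = Hprev[j - 1] + s;
      int H; uint8_t src;
      if (local_query) {
        H = 0; src = 0;
        if (diag > H) { H = diag; src = 1; }
      } else {
        H = diag; src = 1;
      }
      if (E > H) { H = E; src = 2; }
      if (F > H) { H = F; src = 3; }
      Hcur[j] = H;
      tb[(size_t)(i - 1) * m + (j - 1)] = (uint8_t)(t | src);
      if (local_query) {
        if (H > best) { best = H; bi = i; bj = j; }
      } else if (i == n && H > best) {
        best = H; bi = i; bj = j;
      }
    }
    std::swap(Hprev, Hcur);
  }

  SWResult res;
  res.score = best;
  res.matches = res.mismatches = res.gap_cols = 0;
  if ((local_query && best <= 0) || bi < 0) {
    res.score = local_query ? 0 : best;
    res.q_start = res.q_end = res.t_start = res.t_end = 0;
    res.cigar = "";
    return res;
  }
  // traceback
  int i = bi, j = bj;
  std::vector<std::pair<char, int>> ops;
  auto push_op = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back({op, 1});
  };
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0) {
    if (j == 0) {            // glocal: query overhang before the target
      push_op('I');
      res.gap_cols++;
      --i;
      continue;
    }
    uint8_t t = tb[(size_t)(i - 1) * m + (j - 1)];
    if (state == 0) {
      uint8_t src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        push_op('M');
        if (qc[i - 1] == tc[j - 1] && qc[i - 1] < 4) res.matches++;
        else res.mismatches++;
        --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {        // E: gap consuming target (deletion in query)
      push_op('D');
      res.gap_cols++;
      if (!(t & 4)) state = 0;
      --j;
    } else {                        // F: gap consuming query (insertion vs target)
      push_op('I');
      res.gap_cols++;
      if (!(t & 8)) state = 0;
      --i;
    }
  }
  res.q_start = i; res.q_end = bi;
  res.t_start = j; res.t_end = bj;
  std::string cig;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    cig += std::to_string(it->second) + it->first;
  res.cigar = cig;
  return res;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string target,
                  int match, int mismatch, int gap_open, int gap_ext) {
  SWResult r = sw_core(query, target, match, mismatch, gap_open, gap_ext);
  return List::create(
    _["score"] = r.score,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["t_start"] = r.t_start, _["t_end"] = r.t_end,
    _["matches"] = r.matches, _["mismatches"] = r.mismatches,
    _["gap_cols"] = r.gap_cols,
    _["aligned_cols"] = r.matches + r.mismatches,
    _["cigar"] = r.cigar);
}

// ---- k-mer utilities -------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> KmerIndex;

static void index_kmers(const std::string &s, int k, int seq_id, KmerIndex &idx) {
  const int n = (int) s.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c > 3) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) c) & mask;
    if (++valid >= k) idx[kmer].push_back({seq_id, i - k + 1});
  }
}

// exact shared k-mers between query and target (both 0-based start positions)
// [[Rcpp::export]]
List seed_hits_cpp(std::string query, std::string target, int k) {
  KmerIndex idx;
  index_kmers(query, k, 0, idx);
  std::vector<int> qpos, tpos;
  const int n = (int) target.size();
  uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(target[i]);
    if (c > 3) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t) c) & mask;
    if (++valid >= k) {
      auto it = idx.find(kmer);
      if (it != idx.end()) {
        for (auto &p : it->second) {
          qpos.push_back(p.second);
          tpos.push_back(i - k + 1);
        }
      }
    }
  }
  return List::create(_["qpos"] = wrap(qpos), _["tpos"] = wrap(tpos));
}

// ---- short-read mapper -----------------------------------------------------

// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector reads, CharacterVector read_ids,
                        CharacterVector refs, CharacterVector ref_names,
                        int k, double min_identity,
                        int match, int mismatch, int gap_open, int gap_ext,
                        int stride, int pad) {
  const int nref = refs.size();
  std::vector<std::string> ref_seq(nref);
  KmerIndex idx, idx_rescue;
  // rescue tier: disjoint short seeds guarantee (pigeonhole) a clean seed
  // for any read with fewer than read_len/k2 mismatches, catching reads
  // whose mismatches leave no clean k-mer for the primary seeds
  const int k2 = std::min(16, k);
  for (int r = 0; r < nref; ++r) {
    ref_seq[r] = as<std::string>(refs[r]);
    index_kmers(ref_seq[r], k, r, idx);
    if (k2 < k) index_kmers(ref_seq[r], k2, r, idx_rescue);
  }

  const int nr = reads.size();
  std::vector<std::string> out_ref(nr, ""), out_cigar(nr, ""), out_seq(nr, "");
  std::vector<int> out_pos(nr, NA_INTEGER), out_score(nr, NA_INTEGER);
  std::vector<double> out_ident(nr, NA_REAL);
  std::vector<int> out_strand(nr, NA_INTEGER);  // 0 = +, 1 = -
  LogicalVector mapped(nr, false);

  // candidate (ref, diagonal) pairs from exact seeds at the given offsets
  auto collect = [&](const std::string &seq, const KmerIndex &index,
                     int kk, int step) {
    std::vector<std::pair<int, int>> cand;
    int len = (int) seq.size();
    uint64_t m = (kk == 32) ? ~0ULL : ((1ULL << (2 * kk)) - 1);
    for (int o = 0; o <= len - kk; o += step) {
      uint64_t kmer = 0; bool ok = true;
      for (int x = 0; x < kk; ++x) {
        int c = base_code(seq[o + x]);
        if (c > 3) { ok = false; break; }
        kmer = ((kmer << 2) | (uint64_t) c) & m;
      }
      if (ok) {
        auto it = index.find(kmer);
        if (it != index.end())
          for (auto &p : it->second) cand.push_back({p.first, p.second - o});
      }
      if (o + step > len - kk && o != len - kk) o = len - kk - step;  // force last offset
    }
    return cand;
  };

  for (int ri = 0; ri < nr; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int len = (int) fwd.size();
    if (len < k) continue;
    int best_score = -1, best_ref = -1, best_pos = -1, best_strand = 0;
    SWResult best_aln; std::string best_oriented;

    std::string oriented[2] = {fwd, revcomp(fwd)};
    std::vector<std::pair<int, int>> cands[2];
    for (int strand = 0; strand < 2; ++strand)
      cands[strand] = collect(oriented[strand], idx, k, stride);
    if (cands[0].empty() && cands[1].empty() && k2 < k) {
      // no clean primary seed on either strand: disjoint short-seed rescue
      for (int strand = 0; strand < 2; ++strand)
        cands[strand] = collect(oriented[strand], idx_rescue, k2, k2);
    }

    for (int strand = 0; strand < 2; ++strand) {
      const std::string &seq = oriented[strand];
      std::vector<std::pair<int, int>> &cand = cands[strand];
      if (cand.empty()) continue;
      std::sort(cand.begin(), cand.end());
      std::vector<std::pair<int, int>> uniq;
      for (auto &c : cand) {
        if (!uniq.empty() && uniq.back().first == c.first &&
            std::abs(uniq.back().second - c.second) <= 5) continue;
        uniq.push_back(c);
      }
      for (auto &c : uniq) {
        const std::string &rs = ref_seq[c.first];
        int ts = std::max(0, c.second - pad);
        int te = std::min((int) rs.size(), c.second + len + pad);
        if (te <= ts) continue;
        SWResult a = sw_core(seq, rs.substr(ts, te - ts),
                             match, mismatch, gap_open, gap_ext,
                             /* local_query = */ false);
        int cols = a.matches + a.mismatches;
        if (cols == 0) continue;
        double ident = (double) a.matches / cols;
        if (ident < min_identity) continue;
        int gpos = ts + a.t_start;
        bool better = false;
        if (a.score > best_score) better = true;
        else if (a.score == best_score) {
          if (c.first < best_ref) better = true;
          else if (c.first == best_ref && gpos < best_pos) better = true;
        }
        if (better) {
          best_score = a.score; best_ref = c.first; best_pos = gpos;
          best_strand = strand; best_aln = a; best_oriented = seq;
          best_aln.t_start = gpos; best_aln.t_end = ts + a.t_end;
        }
      }
    }

    if (best_score >= 0) {
      mapped[ri] = true;
      out_ref[ri] = as<std::string>(ref_names[best_ref]);
      out_pos[ri] = best_pos;
      out_score[ri] = best_score;
      out_strand[ri] = best_strand;
      int cols = best_aln.matches + best_aln.mismatches;
      out_ident[ri] = (double) best_aln.matches / cols;
      std::string cig;
      if (best_aln.q_start > 0)
        cig += std::to_string(best_aln.q_start) + "S";
      cig += best_aln.cigar;
      if ((int) best_oriented.size() - best_aln.q_end > 0)
        cig += std::to_string((int) best_oriented.size() - best_aln.q_end) + "S";
      // terminal insertions are query overhangs (e.g. reads spanning an
      // insertion junction): report them as soft clips
      {
        size_t p = 0;
        while (p < cig.size() && isdigit(cig[p])) ++p;
        if (p < cig.size() && cig[p] == 'I') cig[p] = 'S';
        if (!cig.empty() && cig.back() == 'I') cig.back() = 'S';
      }
      out_cigar[ri] = cig;
      out_seq[ri] = best_oriented;
    }
  }

  CharacterVector rref(nr), rcig(nr), rseq(nr), rstrand(nr);
  for (int i = 0; i < nr; ++i) {
    if (mapped[i]) {
      rref[i] = out_ref[i]; rcig[i] = out_cigar[i]; rseq[i] = out_seq[i];
      rstrand[i] = out_strand[i] == 0 ? "+" : "-";
    } else {
      rref[i] = NA_STRING; rcig[i] = NA_STRING; rseq[i] = NA_STRING;
      rstrand[i] = NA_STRING;
    }
  }
  return DataFrame::create(
    _["qname"] = clone(read_ids), _["rname"] = rref, _["pos"] = wrap(out_pos),
    _["strand"] = rstrand, _["cigar"] = rcig, _["score"] = wrap(out_score),
    _["identity"] = wrap(out_ident), _["seq"] = rseq, _["mapped"] = mapped,
    _["stringsAsFactors"] = false);
}

// ---- pileup ----------------------------------------------------------------

// seqs are alignment-oriented; pos is 0-based reference start of the aligned
// (non-clipped) part; returns 4 x ref_len counts (rows A, C, G, T)
// [[Rcpp::export]]
IntegerMatrix pileup_cpp(CharacterVector seqs, IntegerVector pos,
                         CharacterVector cigars, CharacterVector ids,
                         int ref_len) {
  IntegerMatrix counts(4, ref_len);
  const int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(cigars[i])) continue;
    std::string seq = as<std::string>(seqs[i]);
    std::string cig = as<std::string>(cigars[i]);
    int rp = pos[i], qp = 0;
    size_t ci = 0;
    while (ci < cig.size()) {
      int num = 0;
      while (ci < cig.size() && isdigit(cig[ci])) num = num * 10 + (cig[ci++] - '0');
      if (ci >= cig.size()) stop("malformed CIGAR for read %s", as<std::string>(ids[i]));
      char op = cig[ci++];
      switch (op) {
        case 'M': case '=': case 'X':
          if (rp + num > ref_len)
            stop("alignment past reference end for read %s", as<std::string>(ids[i]));
          for (int x = 0; x < num; ++x) {
            int c = base_code(seq[qp + x]);
            if (c < 4) counts(c, rp + x)++;
          }
          rp += num; qp += num;
          break;
        case 'D': case 'N':
          rp += num;
          if (rp > ref_len)
            stop("alignment past reference end for read %s", as<std::string>(ids[i]));
          break;
        case 'I': case 'S':
          qp += num;
          break;
        case 'H': case 'P':
          break;
        default:
          stop("unsupported CIGAR op '%c' for read %s", op, as<std::string>(ids[i]));
      }
    }
  }
  return counts;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
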