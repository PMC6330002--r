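#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// base codes: A=0 C=1 G=2 T=3 *=4 N(or anything else)=5
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case '*': return 4;
  default:  return 5;
  }
}

// Per-read CIGAR summary: reference-consumed length, query-consumed length,
// left soft-clip, right soft-clip.
// [[Rcpp::export]]
IntegerMatrix cpp_cigar_stats(CharacterVector cigar) {
  int n = cigar.size();
  IntegerMatrix out(n, 4);
  colnames(out) = CharacterVector::create("ref_len", "query_len", "left_clip", "right_clip");
  for (int i = 0; i < n; i++) {
    const char* p = CHAR(STRING_ELT(cigar, i));
    long rl = 0, ql = 0, lc = 0, rc = 0;
    bool seen_ref = false;
    while (*p) {
      long len = 0;
      while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); p++; }
      char op = *p;
      if (op == 0) stop("malformed CIGAR in record %d", i + 1);
      p++;
      switch (op) {
      case 'M': case '=': case 'X': rl += len; ql += len; seen_ref = true; break;
      case 'D': case 'N': rl += len; seen_ref = true; break;
      case 'I': ql += len; break;
      case 'S': ql += len; if (seen_ref) rc += len; else lc += len; break;
      case 'H': case 'P': break;
      default: stop("unsupported CIGAR op '%c' in record %d", op, i + 1);
      }
    }
    out(i, 0) = (int)rl; out(i, 1) = (int)ql; out(i, 2) = (int)lc; out(i, 3) = (int)rc;
  }
  return out;
}

// Build a pileup over span [span_start, span_end) (0-based half-open).
// Entries are counting-sorted by column; within a column the order follows
// read input order (stable), so the per-column multiset is order-invariant.
// Deletions contribute a '*' entry per deleted locus with quality
// floor(mean(flanking base qualities)).  Soft clips and insertions never
// enter a column; they are reported as side tables for the heuristics and
// rewrite stages.
// [[Rcpp::export]]
List cpp_build_pileup(IntegerVector pos0, CharacterVector cigar, CharacterVector seq,
                      CharacterVector qual, IntegerVector mapq, IntegerVector strand,
                      int span_start, int span_end) {
  int nr = pos0.size();
  long ns = (long)span_end - (long)span_start;
  if (ns < 0) stop("invalid span");
  std::vector<long> counts(ns + 1, 0);

  // pass 1: validate and count entries per column
  for (int i = 0; i < nr; i++) {
    const char* cg = CHAR(STRING_ELT(cigar, i));
    long slen = LENGTH(STRING_ELT(seq, i));
    long qlen = LENGTH(STRING_ELT(qual, i));
    if (slen != qlen)
      stop("SEQ/QUAL length mismatch for read %d (%d vs %d)", i + 1, (int)slen, (int)qlen);
    long r = pos0[i], q = 0;
    const char* p = cg;
    if (*p == '*' && *(p + 1) == 0) stop("read %d has no CIGAR (unmapped?)", i + 1);
    while (*p) {
      long len = 0;
      while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); p++; }
      char op = *p;
      if (op == 0 || len == 0) stop("malformed CIGAR for read %d", i + 1);
      p++;
      switch (op) {
      case 'M': case '=': case 'X': case 'D': {
        long a = r > span_start ? r : span_start;
        long b = (r + len) < span_end ? (r + len) : span_end;
        for (long k = a; k < b; k++) counts[k - span_start]++;
        r += len;
        if (op != 'D') q += len;
        break;
      }
      case 'N': r += len; break;
      case 'I': case 'S': q += len; break;
      case 'H': case 'P': break;
      default: stop("unsupported CIGAR op '%c' in read %d", op, i + 1);
      }
    }
    if (q != slen)
      stop("CIGAR query length (%d) != SEQ length (%d) for read %d", (int)q, (int)slen, i + 1);
  }

  IntegerVector offsets(ns + 1);
  long tot = 0;
  for (long k = 0; k < ns; k++) { offsets[k] = (int)tot; tot += counts[k]; }
  offsets[ns] = (int)tot;

  IntegerVector e_base(tot), e_qual(tot), e_mapq(tot), e_read(tot), e_qpos(tot), e_strand(tot);
  std::vector<long> fill(ns, 0);
  for (long k = 0; k < ns; k++) fill[k] = offsets[k];

  std::vector<int> c_read, c_pos, c_side, c_len;       // soft clips
  std::vector<int> d_read, d_start, d_end, d_type, d_len; // indel events (0=ins,1=del)

  // pass 2: place entries
  for (int i = 0; i < nr; i++) {
    const char* p = CHAR(STRING_ELT(cigar, i));
    const char* sq = CHAR(STRING_ELT(seq, i));
    const char* ql = CHAR(STRING_ELT(qual, i));
    long qlen = LENGTH(STRING_ELT(qual, i));
    long r = pos0[i], q = 0;
    bool seen_ref = false;
    while (*p) {
      long len = 0;
      while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); p++; }
      char op = *p; p++;
      switch (op) {
      case 'M': case '=': case 'X': {
        for (long k = 0; k < len; k++) {
          long pos = r + k;
          if (pos >= span_start && pos < span_end) {
            long at = fill[pos - span_start]++;
            e_base[at] = base_code(sq[q + k]);
            e_qual[at] = (int)(ql[q + k]) - 33;
            e_mapq[at] = mapq[i];
            e_read[at] = i + 1;
            e_qpos[at] = (int)(q + k);
            e_strand[at] = strand[i];
          }
        }
        r += len; q += len; seen_ref = true;
        break;
      }
      case 'D': {
        // deletion quality: floor of the mean of the flanking base qualities
        int lq = q > 0 ? (int)(ql[q - 1]) - 33 : -1;
        int rq = q < qlen ? (int)(ql[q]) - 33 : -1;
        int dq;
        if (lq >= 0 && rq >= 0) dq = (lq + rq) / 2;
        else if (lq >= 0) dq = lq;
        else if (rq >= 0) dq = rq;
        else dq = 0;
        for (long k = 0; k < len; k++) {
          long pos = r + k;
          if (pos >= span_start && pos < span_end) {
            long at = fill[pos - span_start]++;
            e_base[at] = 4;
            e_qual[at] = dq;
            e_mapq[at] = mapq[i];
            e_read[at] = i + 1;
            e_qpos[at] = NA_INTEGER;
            e_strand[at] = strand[i];
          }
        }
        d_read.push_back(i + 1); d_start.push_back((int)r); d_end.push_back((int)(r + len));
        d_type.push_back(1); d_len.push_back((int)len);
        r += len; seen_ref = true;
        break;
      }
      case 'N': r += len; seen_ref = true; break;
      case 'I':
        d_read.push_back(i + 1); d_start.push_back((int)r); d_end.push_back((int)r);
        d_type.push_back(0); d_len.push_back((int)len);
        q += len;
        break;
      case 'S':
        c_read.push_back(i + 1);
        c_pos.push_back((int)r);  // left clip: read start; right clip: one past last aligned base
        c_side.push_back(seen_ref ? 1 : 0);
        c_len.push_back((int)len);
        q += len;
        break;
      case 'H': case 'P': break;
      }
    }
  }

  return List::create(
    _["offsets"] = offsets,
    _["base"] = e_base, _["qual"] = e_qual, _["mapq"] = e_mapq,
    _["read"] = e_read, _["qpos"] = e_qpos, _["strand"] = e_strand,
    _["clip_read"] = wrap(c_read), _["clip_pos"] = wrap(c_pos),
    _["clip_side"] = wrap(c_side), _["clip_len"] = wrap(c_len),
    _["indel_read"] = wrap(d_read), _["indel_start"] = wrap(d_start),
    _["indel_end"] = wrap(d_end), _["indel_type"] = wrap(d_type),
    _["indel_len"] = wrap(d_len));
}

// Diploid 15-genotype caller over {A,C,G,T,*}, flat prior, exact log-space.
// Per informative entry (base != N): qe = min(qual, mapq, cap), e = 10^(-qe/10);
//   hom g  : P(b) = 1-e        if b == g else e/4
//   het g1g2: P(b) = (1-e)/2 + e/8 if b in {g1,g2} else e/4
// raw_conf = -10*log10(1 - posterior(argmax)) capped at 99.
// pen = sum over entries with base not in genotype (and != N) of min(qual, mapq).
// Ties: first genotype in enumeration order (5 homs A..*, then hets in
// lexicographic allele order) wins, i.e. hom-over-het then A<C<G<T<*.
// [[Rcpp::export]]
List cpp_call_columns(IntegerVector offsets, IntegerVector base, IntegerVector qual,
                      IntegerVector mapq, int cap, int mapq_low) {
  int ncol = offsets.size() - 1;
  static const int G1[15] = {0,1,2,3,4, 0,0,0,0, 1,1,1, 2,2, 3};
  static const int G2[15] = {0,1,2,3,4, 1,2,3,4, 2,3,4, 3,4, 4};

  double Lhom[94], Lmis[94], Lhet[94];
  for (int qe = 0; qe <= 93; qe++) {
    double e = std::pow(10.0, -qe / 10.0);
    Lhom[qe] = std::log1p(-e);              // -Inf at qe == 0, handled by IEEE
    Lmis[qe] = std::log(e / 4.0);
    Lhet[qe] = std::log((1.0 - e) / 2.0 + e / 8.0);
  }
  if (cap > 93) cap = 93;

  IntegerVector g1(ncol), g2(ncol), depth(ncol), lowmapq(ncol), nalleles(ncol);
  NumericVector raw(ncol), pen(ncol);
  IntegerMatrix cnt(6, ncol);

  for (int c = 0; c < ncol; c++) {
    int a = offsets[c], b = offsets[c + 1];
    double Shom[5] = {0,0,0,0,0}, Shet[5] = {0,0,0,0,0};
    double totmis = 0.0;
    int ninf = 0, nlow = 0;
    int bc[6] = {0,0,0,0,0,0};
    for (int i = a; i < b; i++) {
      int bb = base[i];
      bc[bb]++;
      if (mapq[i] < mapq_low) nlow++;
      if (bb == 5) continue;
      int qe = qual[i] < mapq[i] ? qual[i] : mapq[i];
      if (qe > cap) qe = cap;
      if (qe < 0) qe = 0;
      ninf++;
      totmis += Lmis[qe];
      Shom[bb] += Lhom[qe] - Lmis[qe];
      Shet[bb] += Lhet[qe] - Lmis[qe];
    }
    depth[c] = b - a;
    lowmapq[c] = nlow;
    int nal = 0;
    for (int k = 0; k < 5; k++) if (bc[k] > 0) nal++;
    nalleles[c] = nal;
    for (int k = 0; k < 6; k++) cnt(k, c) = bc[k];

    if (ninf == 0) { g1[c] = 5; g2[c] = 5; raw[c] = 0.0; pen[c] = 0.0; continue; }

    double ll[15];
    for (int g = 0; g < 15; g++) {
      // group the allele terms first so that structurally symmetric
      // genotypes (equal allele support) tie bit-exactly and the
      // deterministic tie-break (hom first, then A<C<G<T<*) applies
      if (G1[g] == G2[g]) ll[g] = totmis + Shom[G1[g]];
      else ll[g] = totmis + (Shet[G1[g]] + Shet[G2[g]]);
    }
    int best = 0;
    for (int g = 1; g < 15; g++) if (ll[g] > ll[best]) best = g;
    double m = ll[best], s_others = 0.0;
    for (int g = 0; g < 15; g++) {
      if (g == best) continue;
      if (R_finite(ll[g]) || ll[g] > R_NegInf) s_others += std::exp(ll[g] - m);
    }
    double rc;
    if (s_others <= 0.0) rc = 99.0;
    else {
      double one_minus_post = s_others / (1.0 + s_others);
      rc = -10.0 * std::log10(one_minus_post);
      if (rc > 99.0) rc = 99.0;
      if (rc < 0.0) rc = 0.0;
    }
    g1[c] = G1[best]; g2[c] = G2[best]; raw[c] = rc;

    double pn = 0.0;
    for (int i = a; i < b; i++) {
      int bb = base[i];
      if (bb == 5 || bb == G1[best] || bb == G2[best]) continue;
      pn += (qual[i] < mapq[i] ? qual[i] : mapq[i]);
    }
    pen[c] = pn;
  }

  return List::create(_["g1"] = g1, _["g2"] = g2, _["raw_conf"] = raw,
                      _["penalty"] = pen, _["depth"] = depth,
                      _["n_lowmapq"] = lowmapq, _["n_alleles"] = nalleles,
                      _["counts"] = cnt);
}

// Greedy left-to-right P-block: extend the block while (max-min) of the
// block's ORIGINAL values stays <= 2p; on close every position takes
// floor((max+min)/2), so |out - in| <= p everywhere and p = 0 is identity.
// [[Rcpp::export]]
List cpp_pblock(IntegerVector x, int p) {
  int n = x.size();
  IntegerVector out(n);
  std::vector<int> starts;
  if (n == 0) return List::create(_["values"] = out, _["starts"] = wrap(starts));
  int start = 0, mn = x[0], mx = x[0];
  for (int i = 1; i <= n; i++) {
    bool close = (i == n);
    int nmn = mn, nmx = mx;
    if (!close) {
      nmn = x[i] < mn ? x[i] : mn;
      nmx = x[i] > mx ? x[i] : mx;
      if (nmx - nmn > 2 * p) close = true;
    }
    if (close) {
      int rep = (mn + mx) / 2;
      for (int k = start; k < i; k++) out[k] = rep;
      starts.push_back(start + 1);
      if (i < n) { start = i; mn = x[i]; mx = x[i]; }
    } else { mn = nmn; mx = nmx; }
  }
  return List::create(_["values"] = out, _["starts"] = wrap(starts));
}

static void pblock_run(std::vector<int>& q, int lo, int hi, int p) {
  // apply P-block in place to q[lo, hi)
  if (hi - lo <= 0 || p <= 0) return;
  int start = lo, mn = q[lo], mx = q[lo];
  for (int i = lo + 1; i <= hi; i++) {
    bool close = (i == hi);
    int nmn = mn, nmx = mx;
    if (!close) {
      nmn = q[i] < mn ? q[i] : mn;
      nmx = q[i] > mx ? q[i] : mx;
      if (nmx - nmn > 2 * p) close = true;
    }
    if (close) {
      int rep = (mn + mx) / 2;
      for (int k = start; k < i; k++) q[k] = rep;
      if (i < hi) { start = i; mn = q[i]; mx = q[i]; }
    } else { mn = nmn; mx = nmx; }
  }
}

// Rewrite quality strings.  Span arrays (mask/conf/g1/g2) cover
// [span_start, span_start + ns).  mode: 0 = constant low, 1 = quantize,
// 2 = keep.  quant is a 94-long lookup (value -> representative).
// Kept stretches (mask hits and disagree-mode "keep") are P-block smoothed
// when pblock_p > 0; whole-kept reads are returned verbatim.
// [[Rcpp::export]]
CharacterVector cpp_rewrite_reads(IntegerVector pos0, CharacterVector cigar,
                                  CharacterVector seq, CharacterVector qual,
                                  LogicalVector whole_keep, int span_start,
                                  LogicalVector mask, LogicalVector conf,
                                  IntegerVector g1, IntegerVector g2,
                                  int qual_high, int mode, int qual_low,
                                  IntegerVector quant, int pblock_p) {
  int nr = pos0.size();
  long ns = mask.size();
  CharacterVector out(nr);
  std::vector<int> q;
  std::vector<char> keep, buf;

  for (int i = 0; i < nr; i++) {
    if (whole_keep[i]) { out[i] = STRING_ELT(qual, i); continue; }
    const char* cg = CHAR(STRING_ELT(cigar, i));
    const char* sq = CHAR(STRING_ELT(seq, i));
    const char* ql = CHAR(STRING_ELT(qual, i));
    long L = LENGTH(STRING_ELT(qual, i));
    q.assign(L, 0); keep.assign(L, 0);
    for (long k = 0; k < L; k++) q[k] = (int)(ql[k]) - 33;

    long r = pos0[i], qi = 0;
    bool seen_ref = false;
    const char* p = cg;
    while (*p) {
      long len = 0;
      while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); p++; }
      char op = *p; p++;
      switch (op) {
      case 'M': case '=': case 'X': {
        for (long k = 0; k < len; k++) {
          long idx = r + k - span_start;
          if (idx < 0 || idx >= ns)
            stop("no consensus call covering position %d (read %d): pipeline bug",
                 (int)(r + k), i + 1);
          long at = qi + k;
          if (mask[idx]) { keep[at] = 1; continue; }
          int b = base_code(sq[at]);
          if (conf[idx] && (b == g1[idx] || b == g2[idx])) {
            q[at] = qual_high;
          } else {
            if (mode == 0) q[at] = qual_low;
            else if (mode == 1) {
              if (q[at] < 0 || q[at] > 93) stop("quality %d outside [0,93]", q[at]);
              q[at] = quant[q[at]];
            } else keep[at] = 1;
          }
        }
        r += len; qi += len; seen_ref = true;
        break;
      }
      case 'D': case 'N': r += len; seen_ref = true; break;
      case 'I': case 'S': {
        for (long k = 0; k < len; k++) {
          long proj;
          if (op == 'I') proj = r;
          else proj = seen_ref ? (r + k) : (pos0[i] - len + k);
          long idx = proj - span_start;
          long at = qi + k;
          bool masked = (idx >= 0 && idx < ns && mask[idx]);
          if (masked) { keep[at] = 1; continue; }
          if (mode == 0) q[at] = qual_low;
          else if (mode == 1) {
            if (q[at] < 0 || q[at] > 93) stop("quality %d outside [0,93]", q[at]);
            q[at] = quant[q[at]];
          } else keep[at] = 1;
        }
        qi += len;
        break;
      }
      case 'H': case 'P': break;
      }
    }

    if (pblock_p > 0) {
      long k = 0;
      while (k < L) {
        if (!keep[k]) { k++; continue; }
        long j = k;
        while (j < L && keep[j]) j++;
        pblock_run(q, (int)k, (int)j, pblock_p);
        k = j;
      }
    }

    buf.assign(L, 0);
    for (long k = 0; k < L; k++) buf[k] = (char)(q[k] + 33);
    out[i] = Rf_mkCharLen(buf.data(), (int)L);
  }
  return out;
}
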