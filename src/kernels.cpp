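#include <Rcpp.h>
using namespace Rcpp;

// Pooled k-mer window counts over a set of intervals, using the
// precomputed rolling k-mer code of the contig (NA = window contains N).
// [[Rcpp::export]]
IntegerVector count_windows_cpp(IntegerVector code, IntegerVector starts,
                                IntegerVector len, int k, int nbins) {
  IntegerVector out(nbins);
  const int n = starts.size();
  const int ncode = code.size();
  for (int i = 0; i < n; ++i) {
    const int m = len[i] - k + 1;
    if (m <= 0) continue;
    int s = starts[i] - 1;  // 1-based -> 0-based
    if (s < 0) s = 0;
    int e = s + m;
    if (e > ncode) e = ncode;
    for (int p = s; p < e; ++p) {
      const int v = code[p];
      if (v != NA_INTEGER) ++out[v];
    }
  }
  return out;
}

// Batched window counts: one row of counts per column of `starts`
// (background replicate), pooled over all intervals.
// [[Rcpp::export]]
IntegerMatrix count_windows_batch_cpp(IntegerVector code,
                                      IntegerMatrix starts,
                                      IntegerVector len, int k, int nbins) {
  const int n = starts.nrow(), B = starts.ncol();
  const int ncode = code.size();
  IntegerMatrix out(B, nbins);
  const int *pc = code.begin();
  const int *pst = starts.begin();
  int *po = out.begin();
  for (int b = 0; b < B; ++b) {
    const int *col = pst + (size_t)b * n;
    for (int i = 0; i < n; ++i) {
      const int m = len[i] - k + 1;
      if (m <= 0) continue;
      int s = col[i] - 1;
      if (s < 0) s = 0;
      int e = s + m;
      if (e > ncode) e = ncode;
      for (int p = s; p < e; ++p) {
        const int v = pc[p];
        if (v != NA_INTEGER) ++po[(size_t)v * B + b];
      }
    }
  }
  return out;
}

// Hard-core site placement within one gene. Intronic sites draw an
// exponential gap (decay nt) from the downstream exon start; exonic
// sites draw a uniform exonic centre. Each site retries against the
// already-placed sites, then falls back to a uniform draw in the same
// feature class, and finally accepts an overlap (saturated gene).
// Uses R's RNG.
// [[Rcpp::export]]
List place_gene_sites_cpp(IntegerVector intron_start,
                          IntegerVector intron_end,
                          IntegerVector exon_start, IntegerVector exon_end,
                          int gene_start, int gene_end, int n_intronic,
                          int n_exonic, int L, double decay, int max_tries,
                          int strand_plus) {
  const int n_tot = n_intronic + n_exonic;
  IntegerVector out_s(n_tot), out_e(n_tot);
  IntegerVector is_intron(n_tot);
  // 0 = primary-law draw, 1 = uniform fallback, 2 = overlap accepted
  IntegerVector law(n_tot);
  std::vector<int> occ_s, occ_e;

  // introns wide enough for a site, with cumulative length weights
  std::vector<int> iv; std::vector<double> icum;
  double itot = 0;
  for (int j = 0; j < intron_start.size(); ++j) {
    const int il = intron_end[j] - intron_start[j] + 1;
    if (il >= L) { iv.push_back(j); itot += il; icum.push_back(itot); }
  }
  std::vector<double> ecum; double etot = 0;
  for (int j = 0; j < exon_start.size(); ++j) {
    etot += exon_end[j] - exon_start[j] + 1;
    ecum.push_back(etot);
  }
  auto pick = [](const std::vector<double> &cum, double tot) {
    const double u = unif_rand() * tot;
    return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  };
  auto overlaps = [&](int a, int b) {
    for (size_t q = 0; q < occ_s.size(); ++q)
      if (a <= occ_e[q] && b >= occ_s[q]) return true;
    return false;
  };

  int idx = 0;
  for (int i = 0; i < n_tot; ++i) {
    const bool intronic = i < n_intronic;
    int ps = 0, pe = 0;
    bool placed = false;
    int phase_used = 2;
    for (int phase = 0; phase < 2 && !placed; ++phase) {
      for (int t = 0; t < max_tries; ++t) {
        if (intronic) {
          const int j = iv[pick(icum, itot)];
          const int il = intron_end[j] - intron_start[j] + 1;
          int d;
          if (phase == 0) {
            d = (int)(exp_rand() * decay + 0.5);
            if (d > il - L) d = il - L;
          } else {
            d = (int)(unif_rand() * (il - L + 1));
          }
          if (strand_plus) { pe = intron_end[j] - d; ps = pe - L + 1; }
          else { ps = intron_start[j] + d; pe = ps + L - 1; }
        } else {
          const int j = pick(ecum, etot);
          const int el = exon_end[j] - exon_start[j] + 1;
          const int centre = exon_start[j] + (int)(unif_rand() * el);
          ps = centre - L / 2;
          if (ps < gene_start) ps = gene_start;
          if (ps > gene_end - L + 1) ps = gene_end - L + 1;
          pe = ps + L - 1;
        }
        if (!overlaps(ps, pe)) { placed = true; phase_used = phase; break; }
      }
    }
    out_s[idx] = ps; out_e[idx] = pe;
    is_intron[idx] = intronic ? 1 : 0;
    law[idx] = phase_used;
    occ_s.push_back(ps); occ_e.push_back(pe);
    ++idx;
  }
  return List::create(_["start"] = out_s, _["end"] = out_e,
                      _["intronic"] = is_intron, _["law"] = law);
}

// Draw B region- and length-matched background window starts per site.
// Candidate starts are the window positions inside the site's matched
// intervals minus the site-overlapping block; empty candidate sets fall
// back to the whole gene span. Uses R's RNG (deterministic under seed).
// [[Rcpp::export]]
List sample_background_cpp(IntegerVector iv_start, IntegerVector iv_end,
                           IntegerVector iv_off, IntegerVector site_start,
                           IntegerVector site_end, IntegerVector gene_start,
                           IntegerVector gene_end, int B) {
  const int n = site_start.size();
  IntegerMatrix starts(n, B);
  LogicalVector fallback(n);
  IntegerVector n_candidates(n);
  LogicalVector dropped(n);

  std::vector<int> seg_lo, seg_hi;
  for (int i = 0; i < n; ++i) {
    const int L = site_end[i] - site_start[i] + 1;
    const int f1 = site_start[i] - L + 1, f2 = site_end[i];

    // build allowed segments from a span list
    auto build = [&](const int *lo, const int *hi, int m) {
      seg_lo.clear(); seg_hi.clear();
      for (int j = 0; j < m; ++j) {
        const int wlo = lo[j], whi = hi[j] - L + 1;
        if (whi < wlo) continue;
        // left of forbidden block
        int a = wlo, b = std::min(whi, f1 - 1);
        if (b >= a) { seg_lo.push_back(a); seg_hi.push_back(b); }
        // right of forbidden block
        a = std::max(wlo, f2 + 1); b = whi;
        if (b >= a) { seg_lo.push_back(a); seg_hi.push_back(b); }
      }
    };

    const int o0 = iv_off[i], o1 = iv_off[i + 1];
    std::vector<int> lo, hi;
    for (int j = o0; j < o1; ++j) {
      lo.push_back(iv_start[j]); hi.push_back(iv_end[j]);
    }
    build(lo.data(), hi.data(), (int)lo.size());
    double total = 0;
    for (size_t j = 0; j < seg_lo.size(); ++j)
      total += seg_hi[j] - seg_lo[j] + 1;
    if (total == 0) {
      const int gs = gene_start[i], ge = gene_end[i];
      build(&gs, &ge, 1);
      total = 0;
      for (size_t j = 0; j < seg_lo.size(); ++j)
        total += seg_hi[j] - seg_lo[j] + 1;
      fallback[i] = true;
    }
    n_candidates[i] = (int)total;
    if (total == 0) {
      dropped[i] = true;
      for (int b = 0; b < B; ++b) starts(i, b) = NA_INTEGER;
      continue;
    }
    for (int b = 0; b < B; ++b) {
      double u = unif_rand() * total;
      int idx = (int)u;            // 0-based candidate index
      if (idx >= (int)total) idx = (int)total - 1;
      int pos = NA_INTEGER;
      for (size_t j = 0; j < seg_lo.size(); ++j) {
        const int w = seg_hi[j] - seg_lo[j] + 1;
        if (idx < w) { pos = seg_lo[j] + idx; break; }
        idx -= w;
      }
      starts(i, b) = pos;
    }
  }
  return List::create(_["starts"] = starts, _["fallback"] = fallback,
                      _["n_candidates"] = n_candidates,
                      _["dropped"] = dropped);
}
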