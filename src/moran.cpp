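#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Forward-time Moran model with gene conversion.
//
// Each step one individual dies and is replaced by the offspring of another;
// the offspring acquires Poisson(mu*L) point mutations and Poisson(rho_tot)
// gene conversions, each copying a geometric-length fragment from a uniformly
// chosen donor individual.  An optional hotspot multiplies the local
// conversion initiation rate.  Alleles are coded 0..3; mutation draws one of
// the three other alleles.  Uses R's RNG so runs are seed-reproducible.

// [[Rcpp::export]]
IntegerMatrix moran_sim_cpp(int N, int L, double mu, double rho,
                            double mean_frag, int steps,
                            int hotspot_start, int hotspot_end, double hotspot_mult,
                            IntegerVector sample_idx) {
  if (N < 2) stop("N must be >= 2");
  std::vector<uint8_t> pop((size_t)N * L, 0);
  // start from a uniformly random ancestral haplotype shared by all
  std::vector<uint8_t> anc(L);
  for (int j = 0; j < L; ++j) anc[j] = (uint8_t)(unif_rand() * 4.0);
  for (int i = 0; i < N; ++i) std::memcpy(&pop[(size_t)i * L], anc.data(), L);

  const bool has_hot = hotspot_end >= hotspot_start && hotspot_mult != 1.0;
  const int hlen = has_hot ? (hotspot_end - hotspot_start + 1) : 0;
  const double wtot = (double)L + (has_hot ? (hotspot_mult - 1.0) * hlen : 0.0);
  const double rho_tot = rho * wtot;
  const double mu_tot = mu * (double)L;
  const double p_geom = 1.0 / mean_frag; // fragment length = 1 + Geom(p), mean = mean_frag

  for (int s = 0; s < steps; ++s) {
    int parent = (int)(unif_rand() * N);
    int child = (int)(unif_rand() * N);
    while (child == parent) child = (int)(unif_rand() * N);
    uint8_t *ch = &pop[(size_t)child * L];
    std::memcpy(ch, &pop[(size_t)parent * L], L);

    int nmut = (int)R::rpois(mu_tot);
    for (int m = 0; m < nmut; ++m) {
      int pos = (int)(unif_rand() * L);
      ch[pos] = (uint8_t)((ch[pos] + 1 + (int)(unif_rand() * 3.0)) & 3);
    }

    if (rho_tot > 0) {
      int nconv = (int)R::rpois(rho_tot);
      for (int c = 0; c < nconv; ++c) {
        int donor = (int)(unif_rand() * N);
        while (donor == child) donor = (int)(unif_rand() * N);
        int start;
        if (has_hot && unif_rand() < hotspot_mult * hlen / wtot) {
          start = hotspot_start + (int)(unif_rand() * hlen);
        } else {
          start = (int)(unif_rand() * L);
        }
        int len = 1 + (int)R::rgeom(p_geom);
        int end = start + len;
        if (end > L) end = L;
        std::memcpy(ch + start, &pop[(size_t)donor * L] + start, end - start);
      }
    }
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  const int ns = sample_idx.size();
  IntegerMatrix out(ns, L);
  for (int i = 0; i < ns; ++i) {
    const uint8_t *row = &pop[(size_t)(sample_idx[i] - 1) * L];
    for (int j = 0; j < L; ++j) out(i, j) = row[j];
  }
  return out;
}
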