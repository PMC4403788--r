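// Monte Carlo TCSPC engine: excitation cycles with per-step stochastic
// donor deactivation, acceptor blocking/recovery and threshold-based
// termination. Uses R's RNG throughout so that set.seed() makes runs
// bitwise reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Squared minimum-image distance; periodic wrapping per axis only.
static inline double min_image_dist2(const double* p, const double* q,
                                     const double* box, const int* per) {
  double s = 0.0;
  for (int a = 0; a < 3; ++a) {
    double d = p[a] - q[a];
    if (per[a]) d -= box[a] * std::nearbyint(d / box[a]);
    s += d * d;
  }
  return s;
}

// Displace each site by `linker` in a uniform random direction
// (sphere surface), wrapping periodic axes back into the box.
static void place_dyes(const std::vector<double>& sites, int n,
                       double linker, const double* box, const int* per,
                       std::vector<double>& pos) {
  if (linker <= 0.0) { pos = sites; return; }
  for (int i = 0; i < n; ++i) {
    double vx, vy, vz, nrm2;
    do {
      vx = norm_rand(); vy = norm_rand(); vz = norm_rand();
      nrm2 = vx * vx + vy * vy + vz * vz;
    } while (nrm2 < 1e-24);
    double f = linker / std::sqrt(nrm2);
    double p[3] = { sites[3 * i] + vx * f,
                    sites[3 * i + 1] + vy * f,
                    sites[3 * i + 2] + vz * f };
    for (int a = 0; a < 3; ++a) {
      if (per[a]) p[a] -= box[a] * std::floor(p[a] / box[a]);
      pos[3 * i + a] = p[a];
    }
  }
}

// [[Rcpp::export(name = ".run_simulation_cpp")]]
List run_simulation_cpp(NumericMatrix donor_sites,
                        NumericMatrix acceptor_sites,
                        NumericVector box_in, LogicalVector periodic_in,
                        double linker_D, double linker_A,
                        double R0, double tau_D0, double phi_D,
                        double tau_A0, double p_exc,
                        double dt, int n_channels, double photon_threshold,
                        double cutoff_multiplier,
                        bool track_acceptor, bool resample_positions,
                        double max_cycles) {
  const int nD = donor_sites.nrow();
  const int nA = acceptor_sites.nrow();
  double box[3] = { box_in[0], box_in[1], box_in[2] };
  int per[3] = { periodic_in[0] ? 1 : 0, periodic_in[1] ? 1 : 0,
                 periodic_in[2] ? 1 : 0 };

  // Sites as flat row-major arrays.
  std::vector<double> dsite(3 * nD), asite(3 * nA);
  for (int i = 0; i < nD; ++i)
    for (int a = 0; a < 3; ++a) dsite[3 * i + a] = donor_sites(i, a);
  for (int j = 0; j < nA; ++j)
    for (int a = 0; a < 3; ++a) asite[3 * j + a] = acceptor_sites(j, a);

  // Conservative site-based neighbour lists (computed once; the additive
  // linker margin guarantees no displaced pair inside the cutoff is
  // missed).
  const double cutoff = cutoff_multiplier * R0 + linker_D + linker_A;
  const double cutoff2 = cutoff * cutoff;
  std::vector<int> cand;        // flattened candidate acceptor indices
  std::vector<int> cand_off(nD + 1, 0);
  for (int i = 0; i < nD; ++i) {
    for (int j = 0; j < nA; ++j) {
      if (min_image_dist2(&dsite[3 * i], &asite[3 * j], box, per) <= cutoff2)
        cand.push_back(j);
    }
    cand_off[i + 1] = (int) cand.size();
  }
  IntegerVector donors_without;
  for (int i = 0; i < nD; ++i)
    if (cand_off[i + 1] == cand_off[i]) donors_without.push_back(i + 1);

  const double k0 = 1.0 / tau_D0;
  const double k_em = phi_D * k0;
  const double k_nr = (1.0 - phi_D) * k0;
  const double p0 = 1.0 - std::exp(-k0 * dt); // no-acceptor step probability
  const double p_acc = (nA > 0) ? 1.0 - std::exp(-dt / tau_A0) : 0.0;
  const double R02 = R0 * R0;

  std::vector<double> emi(n_channels, 0.0), nonrad(n_channels, 0.0),
      fret(n_channels, 0.0), acc_deact(n_channels, 0.0);
  double cycles = 0.0, excitations = 0.0, fret_total = 0.0,
         acc_deact_total = 0.0, run_max = 0.0;
  bool threshold_reached = false;

  std::vector<double> dpos(3 * nD), apos(3 * nA);
  const bool any_linker = (linker_D > 0.0 || linker_A > 0.0);
  // Frozen-position runs displace once up front; linker-free scenes just
  // use the sites.
  place_dyes(dsite, nD, linker_D, box, per, dpos);
  place_dyes(asite, nA, linker_A, box, per, apos);

  std::vector<int> perm(nD);
  for (int i = 0; i < nD; ++i) perm[i] = i;

  // Per-cycle scratch for the excited donors.
  std::vector<int> exc_idx(nD), exc_ncand(nD), exc_coff(nD);
  std::vector<char> alive(nD);
  std::vector<double> exc_rates;              // flattened FRET rates
  std::vector<unsigned char> aexc(nA, 0);     // acceptor excited flags
  std::vector<int> aexc_list;                 // currently excited acceptors

  while (cycles < max_cycles) {
    if (((long long) cycles & 0x3FFF) == 0) Rcpp::checkUserInterrupt();

    // Step 4: redraw all dye positions for this excitation cycle.
    if (resample_positions && any_linker) {
      place_dyes(dsite, nD, linker_D, box, per, dpos);
      place_dyes(asite, nA, linker_A, box, per, apos);
    }

    // Step 3: excite a random donor subset, at least one, in the order of
    // the assigned random values (zero-truncated binomial count, uniform
    // subset, uniform order -- distributionally identical to redrawing
    // the whole assignment until someone is excited).
    int k;
    if (p_exc >= 1.0) {
      k = nD;
    } else {
      do { k = (int) R::rbinom((double) nD, p_exc); } while (k == 0);
    }
    for (int i = 0; i < k; ++i) {
      int j = i + (int) (unif_rand() * (nD - i));
      if (j >= nD) j = nD - 1;
      std::swap(perm[i], perm[j]);
    }

    // Step 1/5: FRET rates of each excited donor to its candidate
    // acceptors at this cycle's dye positions.
    exc_rates.clear();
    for (int i = 0; i < k; ++i) {
      int d = perm[i];
      exc_idx[i] = d;
      alive[i] = 1;
      exc_coff[i] = (int) exc_rates.size();
      int nc = cand_off[d + 1] - cand_off[d];
      exc_ncand[i] = nc;
      for (int c = 0; c < nc; ++c) {
        int j = cand[cand_off[d] + c];
        double r2 = min_image_dist2(&dpos[3 * d], &apos[3 * j], box, per);
        double q = R02 / r2;
        exc_rates.push_back(k0 * q * q * q);
      }
    }
    int n_alive = k;

    // Steps 6-11: march through the TCSPC channels.
    for (int t = 0; t < n_channels; ++t) {
      // Step 6: acceptor recovery first; acceptors excited during this
      // step are appended afterwards, so they become eligible only in the
      // next step.
      for (size_t ii = 0; ii < aexc_list.size();) {
        if (unif_rand() < p_acc) {
          aexc[aexc_list[ii]] = 0;
          acc_deact[t] += 1.0;
          acc_deact_total += 1.0;
          aexc_list[ii] = aexc_list.back();
          aexc_list.pop_back();
        } else {
          ++ii;
        }
      }

      // Steps 7-9: excited donors, in excitation order.
      for (int i = 0; i < k; ++i) {
        if (!alive[i]) continue;
        int nc = exc_ncand[i];
        double pd, K = k0;
        if (nc == 0) {
          pd = p0;
        } else {
          const double* rates = &exc_rates[exc_coff[i]];
          const int* cj = &cand[cand_off[exc_idx[i]]];
          for (int c = 0; c < nc; ++c)
            if (!aexc[cj[c]]) K += rates[c];
          pd = 1.0 - std::exp(-K * dt);
        }
        if (unif_rand() >= pd) continue;
        // Deactivation: pick the channel in proportion to the rates of
        // the currently available channels.
        alive[i] = 0;
        --n_alive;
        double v = unif_rand() * K;
        if (v < k_em) {
          emi[t] += 1.0;
          if (emi[t] > run_max) run_max = emi[t];
        } else if (v < k_em + k_nr || nc == 0) {
          nonrad[t] += 1.0;
        } else {
          v -= k_em + k_nr;
          const double* rates = &exc_rates[exc_coff[i]];
          const int* cj = &cand[cand_off[exc_idx[i]]];
          int chosen = -1;
          for (int c = 0; c < nc; ++c) {
            if (aexc[cj[c]]) continue;
            chosen = cj[c];
            v -= rates[c];
            if (v < 0) break;
          }
          if (chosen >= 0) {
            // Step 11: the acceptor takes the quantum and is blocked.
            aexc[chosen] = 1;
            aexc_list.push_back(chosen);
            fret[t] += 1.0;
            fret_total += 1.0;
          } else {
            // No acceptor was available despite a FRET draw (can only
            // happen through floating-point round-off); count as
            // non-radiative.
            nonrad[t] += 1.0;
          }
        }
      }
      if (n_alive == 0 && !track_acceptor) break;
    }

    // Acceptors still excited at the window end simply expire (the
    // repetition period is far longer than the lifetimes).
    for (size_t ii = 0; ii < aexc_list.size(); ++ii) aexc[aexc_list[ii]] = 0;
    aexc_list.clear();

    cycles += 1.0;
    excitations += (double) k;
    // Step 2: threshold test after each completed cycle.
    if (run_max >= photon_threshold) { threshold_reached = true; break; }
  }

  return List::create(
    _["emission"] = NumericVector(emi.begin(), emi.end()),
    _["nonradiative"] = NumericVector(nonrad.begin(), nonrad.end()),
    _["fret"] = NumericVector(fret.begin(), fret.end()),
    _["acceptor_deactivation"] = NumericVector(acc_deact.begin(),
                                               acc_deact.end()),
    _["cycles"] = cycles,
    _["excitations"] = excitations,
    _["fret_total"] = fret_total,
    _["acceptor_deactivations_total"] = acc_deact_total,
    _["donors_without_acceptor"] = donors_without,
    _["threshold_reached"] = threshold_reached,
    _["max_bin_count"] = run_max);
}
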