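// Exact (direct-method) stochastic simulation of the four-state Hsp70
// cycle in a finite volume. Nucleotides are chemostatted, so exchange and
// hydrolysis enter as effective first-order channels. Hydrolysis events
// are identified by thinning the combined ATP->ADP channels with
// probability k_h / k_TD (and k_h_S / k_TD_S), so the dissipative flux is
// measurable without extra reactions.
//
// Uses R's RNG (unif_rand via Rcpp) so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List ssa_cycle(NumericVector rate, // konT,koffT,konD,koffD,kTD,kDT,kTDS,kDTS,kh,khS
               IntegerVector init, // nT, nD, nTS, nDS, nS
               double conv,        // 1/(N_A * V): copies -> M
               double t_burn, double t_sample, int n_blocks,
               int max_record, int record_thin) {
  const double konT = rate[0], koffT = rate[1], konD = rate[2],
               koffD = rate[3], kTD = rate[4], kDT = rate[5],
               kTDS = rate[6], kDTS = rate[7], kh = rate[8], khS = rate[9];
  const double p_h = (kTD > 0.0) ? kh / kTD : 0.0;
  const double p_hS = (kTDS > 0.0) ? khS / kTDS : 0.0;

  double nT = init[0], nD = init[1], nTS = init[2], nDS = init[3], nS = init[4];
  const double t_end = t_burn + t_sample;
  const double block_len = t_sample / n_blocks;

  // per-block time integrals of the five copy numbers + hydrolysis counts
  NumericMatrix block_occ(n_blocks, 5);
  NumericVector block_hyd(n_blocks);

  std::vector<double> rec_t;
  std::vector<int> rec_T, rec_D, rec_TS, rec_DS, rec_S;
  std::vector<double> rec_hyd;
  rec_t.reserve(std::min(max_record, 1 << 16));

  double t = 0.0, hyd_count = 0.0;
  long long n_events = 0;
  bool halted = false;

  auto record = [&](double tt) {
    if ((int)rec_t.size() < max_record) {
      rec_t.push_back(tt);
      rec_T.push_back((int)nT); rec_D.push_back((int)nD);
      rec_TS.push_back((int)nTS); rec_DS.push_back((int)nDS);
      rec_S.push_back((int)nS);
      rec_hyd.push_back(hyd_count);
    }
  };
  record(0.0);

  auto accumulate = [&](double t0, double t1) {
    // add occupancy * dwell over [t0, t1) to the sampling blocks
    double a = std::max(t0, t_burn);
    if (a >= t1) return;
    while (a < t1) {
      int b = (int)std::floor((a - t_burn) / block_len);
      if (b >= n_blocks) b = n_blocks - 1;
      double b_end = t_burn + (b + 1) * block_len;
      double seg = std::min(t1, b_end) - a;
      block_occ(b, 0) += nT * seg;  block_occ(b, 1) += nD * seg;
      block_occ(b, 2) += nTS * seg; block_occ(b, 3) += nDS * seg;
      block_occ(b, 4) += nS * seg;
      a += seg;
      if (seg <= 0.0) break; // paranoia against FP stagnation
    }
  };

  while (t < t_end) {
    double a1 = konT * conv * nT * nS;
    double a2 = koffT * nTS;
    double a3 = konD * conv * nD * nS;
    double a4 = koffD * nDS;
    double a5 = kTD * nT;
    double a6 = kDT * nD;
    double a7 = kTDS * nTS;
    double a8 = kDTS * nDS;
    double a0 = a1 + a2 + a3 + a4 + a5 + a6 + a7 + a8;
    if (a0 <= 0.0) { // absorbing state: freeze until t_end
      accumulate(t, t_end);
      t = t_end;
      halted = true;
      break;
    }
    double dt = -std::log(unif_rand()) / a0;
    double t_next = t + dt;
    accumulate(t, std::min(t_next, t_end));
    if (t_next >= t_end) { t = t_end; break; }
    t = t_next;

    double u = unif_rand() * a0;
    if (u < a1)                { nT--; nS--; nTS++; }
    else if (u < a1+a2)        { nTS--; nT++; nS++; }
    else if (u < a1+a2+a3)     { nD--; nS--; nDS++; }
    else if (u < a1+a2+a3+a4)  { nDS--; nD++; nS++; }
    else if (u < a1+a2+a3+a4+a5) {
      nT--; nD++;
      if (unif_rand() < p_h) {
        hyd_count += 1.0;
        if (t >= t_burn) {
          int b = (int)std::floor((t - t_burn) / block_len);
          if (b >= n_blocks) b = n_blocks - 1;
          block_hyd[b] += 1.0;
        }
      }
    }
    else if (u < a1+a2+a3+a4+a5+a6) { nD--; nT++; }
    else if (u < a1+a2+a3+a4+a5+a6+a7) {
      nTS--; nDS++;
      if (unif_rand() < p_hS) {
        hyd_count += 1.0;
        if (t >= t_burn) {
          int b = (int)std::floor((t - t_burn) / block_len);
          if (b >= n_blocks) b = n_blocks - 1;
          block_hyd[b] += 1.0;
        }
      }
    }
    else { nDS--; nTS++; }

    n_events++;
    if (n_events % record_thin == 0) record(t);
    if (n_events % 1048576 == 0) Rcpp::checkUserInterrupt();
  }
  record(t);

  return List::create(
    _["times"] = wrap(rec_t),
    _["T"] = wrap(rec_T), _["D"] = wrap(rec_D),
    _["TS"] = wrap(rec_TS), _["DS"] = wrap(rec_DS),
    _["S"] = wrap(rec_S),
    _["hydrolysis_cum"] = wrap(rec_hyd),
    _["block_occupancy"] = block_occ,
    _["block_hydrolysis"] = block_hyd,
    _["block_length"] = block_len,
    _["hydrolysis_events"] = hyd_count,
    _["n_events"] = (double)n_events,
    _["halted"] = halted,
    _["final"] = NumericVector::create(nT, nD, nTS, nDS, nS),
    _["t_final"] = t);
}
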