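// Monte Carlo lifetime simulator for the female strategies. Uses R's RNG so
// results are reproducible via set.seed() from R. Events mirror the branch
// structure of the closed-form renewal equations exactly: offspring are
// credited at the start of a cycle, yearly survival is Bernoulli(sf) with a
// Bernoulli(sf^frac) draw for fractional cycle remainders, and a CM-CM pair
// persists while both mothers survive their cycles independently.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline bool survive_cycle(double len, double sf) {
  int whole = (int)std::floor(len);
  for (int i = 0; i < whole; ++i)
    if (unif_rand() >= sf) return false;
  double frac = len - whole;
  if (frac > 0.0 && unif_rand() >= std::pow(sf, frac)) return false;
  return true;
}

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

// strategy: 0 = IM, 1 = OM, 2 = CM
// care is realized once per lifetime: care_hi with probability p_care_hi
// (mate is a partnered Coalition Male), else care_lo.
// p_meet_* is the focal female's meeting distribution (assortment included).
// [[Rcpp::export]]
IntegerVector cpp_lifetime_totals(int n, int strategy, double s0, double sf,
                                  double b_allo, double T_ibi, double delta,
                                  double care_hi, double care_lo,
                                  double p_care_hi, double p_meet_cm,
                                  double p_meet_om, double p_meet_im) {
  IntegerVector totals(n);
  const double cyc_long = T_ibi;
  const double cyc_short = T_ibi - delta;
  for (int rep = 0; rep < n; ++rep) {
    double care = (unif_rand() < p_care_hi) ? care_hi : care_lo;
    double S_im = clamp01(s0 + care);
    double S_allo = clamp01(s0 + b_allo + care);
    int total = 0;
    if (strategy == 0) {                       // Independent Mother
      for (;;) {
        if (unif_rand() < S_im) ++total;
        if (!survive_cycle(cyc_long, sf)) break;
      }
    } else if (strategy == 1) {                // Opportunistic Mother
      for (;;) {
        double u = unif_rand();
        if (u < p_meet_cm && unif_rand() < 0.5) {
          // exploits the Cooperative Mother: allo benefit, short cycle
          if (unif_rand() < S_allo) ++total;
          if (!survive_cycle(cyc_short, sf)) break;
        } else {
          // CM reproduces first and the OM refuses to allo-parent, or the
          // interactant is an OM/IM: an independent cycle either way
          if (unif_rand() < S_im) ++total;
          if (!survive_cycle(cyc_long, sf)) break;
        }
      }
    } else {                                   // Cooperative Mother
      bool paired = false;
      bool alive = true;
      while (alive) {
        if (!paired) {
          double u = unif_rand();
          if (u < p_meet_cm) {
            paired = true;                     // search costs no time
          } else if (u < p_meet_cm + p_meet_om) {
            if (unif_rand() < 0.5) {
              // sucker's payoff: an allomothering period, no own offspring
              if (!survive_cycle(cyc_short, sf)) alive = false;
            } else {
              if (unif_rand() < S_im) ++total;
              if (!survive_cycle(cyc_long, sf)) alive = false;
            }
          } else {
            if (unif_rand() < S_im) ++total;
            if (!survive_cycle(cyc_long, sf)) alive = false;
          }
        } else {
          if (unif_rand() < S_allo) ++total;
          if (!survive_cycle(cyc_short, sf)) { alive = false; break; }
          if (!survive_cycle(cyc_short, sf)) paired = false;  // partner died
        }
      }
    }
    totals[rep] = total;
  }
  return totals;
}
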