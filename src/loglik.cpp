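#include <Rcpp.h>
using namespace Rcpp;

// Session log-likelihood for the classify-refine / classic learning cores.
// Mirrors the R reference path (init_beliefs / update_beliefs / trial_loglik)
// exactly; exists because MAP fitting needs ~1e4 evaluations per session.
//
// par: the 12 parameters in canonical order
//   0 pHI0, 1 pSI0, 2 dEv, 3 EvRat, 4 alphaPrec, 5 wH, 6 wS, 7 w0,
//   8 lambda_other, 9 aEv, 10 omega, 11 POCbias
// outcomes: blocks x trials, 1 = fair split
// *_bin: blocks x trials nearest-bin indices (1-based) of the three reports
// channels: (expectation, HI, SI) inclusion flags
// classic: 0 = classify-refine (2x2, refineable), 1 = classic (6x6, fixed)

static inline double logistic_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double poc_adjust(double m, double bias, bool nonwhite) {
  if (!nonwhite || bias == 0.0) return m;
  double v = std::min(std::max(m, 1e-6), 1.0 - 1e-6);
  return logistic_(std::log(v / (1.0 - v)) + bias);
}

// log p(report bin | model value) under the squared-distance softmax channel
static inline double channel_loglik(double m, double alpha,
                                    const NumericVector &bins, int bin1) {
  int nb = bins.size();
  double mind2 = R_PosInf;
  for (int b = 0; b < nb; ++b) {
    double d2 = (bins[b] - m) * (bins[b] - m);
    if (d2 < mind2) mind2 = d2;
  }
  double tot = 0.0, pb = 0.0;
  for (int b = 0; b < nb; ++b) {
    double d2 = (bins[b] - m) * (bins[b] - m);
    double w = std::exp(-alpha * (d2 - mind2));
    tot += w;
    if (b == bin1 - 1) pb = w;
  }
  double p = pb / tot;
  return std::log(p > 1e-12 ? p : 1e-12);
}

// [[Rcpp::export(name = ".session_loglik_cpp")]]
double session_loglik_cpp(NumericVector par, IntegerMatrix outcomes,
                          IntegerVector nonwhite, IntegerMatrix exp_bin,
                          IntegerMatrix hi_bin, IntegerMatrix si_bin,
                          NumericVector bin_values, int classic,
                          LogicalVector channels) {
  const double pHI0 = par[0], pSI0 = par[1], dEv = par[2], EvRat = par[3],
               alpha = par[4], wH = par[5], wS = par[6], w0 = par[7],
               lambda = par[8], aEv = par[9], omega = par[10], bias = par[11];
  const int nB = outcomes.nrow(), nT = outcomes.ncol();
  const bool use_exp = channels[0], use_hi = channels[1], use_si = channels[2];

  int nh, ns;
  std::vector<double> hvals, svals;
  if (classic) {
    nh = ns = 6;
    for (int i = 0; i < 6; ++i) {
      double v = (2.0 * (i + 1) - 1.0) / 12.0;
      hvals.push_back(v);
      svals.push_back(v);
    }
  } else {
    nh = ns = 2;
    hvals = {0.05, 0.95};
    svals = {0.05, 0.95};
  }
  const int S = nh * ns;

  // marginal priors per dimension
  std::vector<double> hm(nh), sm(ns);
  if (classic) {
    double ch = dEv * EvRat, cs = dEv;
    double ah = pHI0 * ch, bh = (1.0 - pHI0) * ch;
    double as = pSI0 * cs, bs = (1.0 - pSI0) * cs;
    double th = 0.0, ts = 0.0;
    bool ok_h = true, ok_s = true;
    for (int i = 0; i < nh; ++i) {
      hm[i] = R::dbeta(hvals[i], ah, bh, 0);
      if (!R_finite(hm[i])) ok_h = false;
      th += hm[i];
    }
    for (int i = 0; i < ns; ++i) {
      sm[i] = R::dbeta(svals[i], as, bs, 0);
      if (!R_finite(sm[i])) ok_s = false;
      ts += sm[i];
    }
    if (!ok_h || th <= 0) { // degenerate concentration: nearest-point mass
      int best = 0;
      for (int i = 1; i < nh; ++i)
        if (std::fabs(hvals[i] - pHI0) < std::fabs(hvals[best] - pHI0)) best = i;
      for (int i = 0; i < nh; ++i) hm[i] = (i == best) ? 1.0 : 0.0;
      th = 1.0;
    }
    if (!ok_s || ts <= 0) {
      int best = 0;
      for (int i = 1; i < ns; ++i)
        if (std::fabs(svals[i] - pSI0) < std::fabs(svals[best] - pSI0)) best = i;
      for (int i = 0; i < ns; ++i) sm[i] = (i == best) ? 1.0 : 0.0;
      ts = 1.0;
    }
    for (int i = 0; i < nh; ++i) hm[i] /= th;
    for (int i = 0; i < ns; ++i) sm[i] /= ts;
  } else {
    hm[0] = 1.0 - pHI0; hm[1] = pHI0;
    sm[0] = 1.0 - pSI0; sm[1] = pSI0;
  }

  // joint layout (hi slowest), policy fairness, initial prior
  std::vector<double> policy(S), prior0(S);
  std::vector<int> hi_idx(S), si_idx(S);
  for (int ih = 0; ih < nh; ++ih) {
    for (int is = 0; is < ns; ++is) {
      int s = ih * ns + is;
      hi_idx[s] = ih; si_idx[s] = is;
      policy[s] = logistic_(w0 - wH * hvals[ih] - wS * svals[is]);
      prior0[s] = hm[ih] * sm[is];
    }
  }

  std::vector<double> base_f(S), base_u(S), cnt_f(S), cnt_u(S);
  if (!classic) {
    for (int s = 0; s < S; ++s) {
      base_f[s] = aEv * policy[s];
      base_u[s] = aEv * (1.0 - policy[s]);
      cnt_f[s] = base_f[s];
      cnt_u[s] = base_u[s];
    }
  }

  std::vector<double> prior(S), post(S), pf(S);
  double ll = 0.0;

  for (int b = 0; b < nB; ++b) {
    prior = prior0; // fresh state prior each dictator
    if (!classic && b > 0) { // carry-over of refined counts
      for (int s = 0; s < S; ++s) {
        cnt_f[s] = base_f[s] + lambda * (cnt_f[s] - base_f[s]);
        cnt_u[s] = base_u[s] + lambda * (cnt_u[s] - base_u[s]);
      }
    }
    bool nw = nonwhite[b] != 0;
    for (int t = 0; t < nT; ++t) {
      // outcome likelihood per state
      if (classic) {
        for (int s = 0; s < S; ++s) pf[s] = policy[s];
      } else {
        for (int s = 0; s < S; ++s) pf[s] = cnt_f[s] / (cnt_f[s] + cnt_u[s]);
      }
      if (use_exp) {
        double pred = 0.0;
        for (int s = 0; s < S; ++s) pred += prior[s] * pf[s];
        ll += channel_loglik(pred, alpha, bin_values, exp_bin(b, t));
      }
      // Bayes step
      int fair = outcomes(b, t);
      double tot = 0.0;
      for (int s = 0; s < S; ++s) {
        post[s] = prior[s] * (fair ? pf[s] : (1.0 - pf[s]));
        tot += post[s];
      }
      if (!(tot > 0.0) || !R_finite(tot)) return R_NegInf;
      for (int s = 0; s < S; ++s) post[s] /= tot;
      // credit + forgetting (classify-refine only)
      if (!classic) {
        for (int s = 0; s < S; ++s) {
          if (fair) cnt_f[s] += post[s]; else cnt_u[s] += post[s];
          cnt_f[s] = base_f[s] + omega * (cnt_f[s] - base_f[s]);
          cnt_u[s] = base_u[s] + omega * (cnt_u[s] - base_u[s]);
        }
      }
      // attribution channels
      if (use_hi || use_si) {
        double mhi = 0.0, msi = 0.0;
        if (classic) {
          for (int s = 0; s < S; ++s) {
            mhi += post[s] * hvals[hi_idx[s]];
            msi += post[s] * svals[si_idx[s]];
          }
        } else {
          for (int s = 0; s < S; ++s) {
            if (hi_idx[s] == nh - 1) mhi += post[s];
            if (si_idx[s] == ns - 1) msi += post[s];
          }
        }
        if (use_hi)
          ll += channel_loglik(poc_adjust(mhi, bias, nw), alpha, bin_values,
                               hi_bin(b, t));
        if (use_si)
          ll += channel_loglik(poc_adjust(msi, bias, nw), alpha, bin_values,
                               si_bin(b, t));
      }
      prior = post;
    }
  }
  return ll;
}
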