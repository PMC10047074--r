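#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs for the cloned hierarchical fitness
// models. Families: 0 gaussian (toy/linear), 1 ri (truncated-below-zero,
// censored-above-U normal), 2 death (geometric survival, censored at the
// horizon), 3 afr (negative binomial size 4, response shifted by the
// minimum age at maturity), 4 wait (geometric, response shifted by one).
//
// Cloning: observations are implicitly replicated K times; latent blocks
// (per-individual F, per-year gamma/theta) carry one column per clone;
// structural parameters (betas, sigmas) are shared.

static inline double l1pe(double x) {  // log(1 + e^x), stable
  if (x > 35.0) return x;
  if (x < -20.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double lse2(double a, double b) {  // log(e^a + e^b)
  if (a > b) return a + l1pe(b - a);
  return b + l1pe(a - b);
}

static inline double obs_ll(int family, double y, int cens, double eta,
                            double sigma, double U, double horizon,
                            int leftTrunc) {
  switch (family) {
  case 0:  // gaussian
    return R::dnorm(y, eta, sigma, 1);
  case 1: { // ri: truncated below 0, censored above U
    double lnorm = R::pnorm(eta / sigma, 0.0, 1.0, 1, 1); // log P(Y > 0)
    if (cens)
      return R::pnorm((eta - U) / sigma, 0.0, 1.0, 1, 1) - lnorm;
    return R::dnorm(y, eta, sigma, 1) - lnorm;
  }
  case 2: { // death: d years survived then death; censored = alive at horizon
    double ls = -l1pe(eta);               // log s, s = 1/(1+e^eta)
    double l1ms = eta + ls;               // log(1-s)
    double ll = cens ? horizon * ls : y * ls + l1ms;
    if (leftTrunc) ll -= 4.0 * ls;        // condition on surviving to age 4
    return ll;
  }
  case 3: { // afr: NB(4, p), k = afr - 4, link 4(1-p)/p = e^eta
    double k = y - 4.0;
    double lden = lse2(std::log(4.0), eta);       // log(4 + e^eta)
    double lp = std::log(4.0) - lden;             // log p
    double l1mp = eta - lden;                     // log(1-p)
    return R::lchoose(k + 3.0, k) + 4.0 * lp + k * l1mp;
  }
  case 4: { // wait: geometric, k = w - 1, link (1-pi)/pi = e^eta
    double k = y - 1.0;
    double lpi = -l1pe(eta);               // log pi
    double l1mpi = eta + lpi;              // log(1-pi)
    return k * l1mpi + lpi;
  }
  }
  return NA_REAL;
}

struct Model {
  int family, nObs, nInd, nYears, K;
  int hasINB, hasCOL, hasINT, hasFIRST, yearIcpt, yearSlope, leftTrunc;
  NumericVector y, col, first, A, Bv, fixedF;
  IntegerVector cens, year, ind;
  NumericMatrix X;          // gaussian design
  double U, horizon, sigmaFixed;
};

static double eta_of(const Model &M, const std::vector<double> &beta,
                     const std::vector<double> &gamma,
                     const std::vector<double> &theta,
                     const std::vector<double> &F, int j, int k) {
  if (M.family == 0) {
    double e = 0.0;
    for (int c = 0; c < M.X.ncol(); ++c) e += M.X(j, c) * beta[c];
    return e;
  }
  double e = beta[0];
  double Fi = 0.0;
  if (M.hasINB) Fi = F[(size_t)M.ind[j] * M.K + k];
  double slope = M.hasINB ? beta[1] : 0.0;
  if (M.yearSlope) slope += theta[(size_t)M.year[j] * M.K + k];
  e += slope * Fi;
  int pos = M.hasINB ? 2 : 1;
  if (M.hasCOL) { e += beta[pos] * M.col[j]; ++pos; }
  if (M.hasINT) { e += beta[pos] * Fi * M.col[j]; ++pos; }
  if (M.hasFIRST) { e += beta[pos] * M.first[j]; ++pos; }
  if (M.yearIcpt) e += gamma[(size_t)M.year[j] * M.K + k];
  return e;
}

static inline double halfCauchyLog(double x, double scale) {
  if (x <= 0) return R_NegInf;
  return std::log(2.0 / (M_PI * scale)) - std::log1p((x / scale) * (x / scale));
}

// [[Rcpp::export]]
List mwg_chain(List dat, List spec, List priors, List init, List ctrl) {
  Model M;
  M.family   = as<int>(dat["family"]);
  M.y        = as<NumericVector>(dat["y"]);
  M.cens     = as<IntegerVector>(dat["cens"]);
  M.col      = as<NumericVector>(dat["col"]);
  M.first    = as<NumericVector>(dat["first"]);
  M.year     = as<IntegerVector>(dat["year"]);
  M.ind      = as<IntegerVector>(dat["ind"]);
  M.A        = as<NumericVector>(dat["A"]);
  M.Bv       = as<NumericVector>(dat["B"]);
  M.X        = as<NumericMatrix>(dat["X"]);
  M.U        = as<double>(dat["U"]);
  M.horizon  = as<double>(dat["horizon"]);
  M.sigmaFixed = as<double>(dat["sigmaFixed"]);
  M.nObs     = M.y.size();
  M.nInd     = M.A.size();
  M.nYears   = as<int>(dat["nYears"]);
  M.K        = as<int>(ctrl["K"]);
  M.hasINB   = as<int>(spec["hasINB"]);
  M.hasCOL   = as<int>(spec["hasCOL"]);
  M.hasINT   = as<int>(spec["hasINT"]);
  M.hasFIRST = as<int>(spec["hasFIRST"]);
  M.yearIcpt = as<int>(spec["yearIcpt"]);
  M.yearSlope= as<int>(spec["yearSlope"]);
  M.leftTrunc= as<int>(spec["leftTrunc"]);

  const int K = M.K;
  const int nBeta = (M.family == 0) ? M.X.ncol()
    : 1 + M.hasINB + M.hasCOL + M.hasINT + M.hasFIRST;
  const bool sampleSigmaR =
    (M.family == 1) || (M.family == 0 && !R_finite(M.sigmaFixed));

  const double betaVar   = as<double>(priors["betaVar"]);
  const double b0Lower   = as<double>(priors["b0Lower"]);
  const double b0Upper   = as<double>(priors["b0Upper"]);
  const double sigmaRScale = as<double>(priors["sigmaRScale"]);
  const std::string sgType = as<std::string>(priors["sigmaGammaType"]);
  const double sgScale   = as<double>(priors["sigmaGammaScale"]);
  const double sgUpper   = as<double>(priors["sigmaGammaUpper"]);
  const double stUpper   = as<double>(priors["sigmaThetaUpper"]);

  const int nIter = as<int>(ctrl["nIter"]);
  const int burn  = as<int>(ctrl["burn"]);
  const int thin  = as<int>(ctrl["thin"]);
  const int adaptUntil = as<int>(ctrl["adaptUntil"]);

  // state
  std::vector<double> beta = as< std::vector<double> >(init["beta"]);
  double sigmaR  = as<double>(init["sigmaR"]);
  double sigmaG  = as<double>(init["sigmaGamma"]);
  double sigmaT  = as<double>(init["sigmaTheta"]);
  std::vector<double> gamma((size_t)std::max(1, M.nYears) * K, 0.0);
  std::vector<double> theta((size_t)std::max(1, M.nYears) * K, 0.0);
  {
    NumericVector g0 = as<NumericVector>(init["gamma"]);
    NumericVector t0 = as<NumericVector>(init["theta"]);
    if (M.yearIcpt)
      for (int yy = 0; yy < M.nYears; ++yy)
        for (int k = 0; k < K; ++k) gamma[(size_t)yy * K + k] = g0[yy];
    if (M.yearSlope)
      for (int yy = 0; yy < M.nYears; ++yy)
        for (int k = 0; k < K; ++k) theta[(size_t)yy * K + k] = t0[yy];
  }
  std::vector<double> F((size_t)M.nInd * K, 0.0);
  {
    NumericVector F0 = as<NumericVector>(init["F"]);
    for (int i = 0; i < M.nInd; ++i)
      for (int k = 0; k < K; ++k) F[(size_t)i * K + k] = F0[i];
  }
  double sigma0 = R_finite(M.sigmaFixed) ? M.sigmaFixed : sigmaR;

  // obs index by individual and by year
  std::vector< std::vector<int> > obsOfInd(M.nInd), obsOfYear(std::max(1, M.nYears));
  for (int j = 0; j < M.nObs; ++j) {
    if (M.family != 0) obsOfInd[M.ind[j]].push_back(j);
    if (M.nYears > 0 && M.year[j] >= 0) obsOfYear[M.year[j]].push_back(j);
  }

  // eta cache (nObs x K)
  std::vector<double> eta((size_t)M.nObs * K);
  auto sig = [&]() { return sampleSigmaR && M.family == 1 ? sigmaR :
                     (M.family == 0 ? (R_finite(M.sigmaFixed) ? M.sigmaFixed : sigmaR) : 1.0); };
  auto refresh_eta = [&]() {
    for (int j = 0; j < M.nObs; ++j)
      for (int k = 0; k < K; ++k)
        eta[(size_t)j * K + k] = eta_of(M, beta, gamma, theta, F, j, k);
  };
  refresh_eta();

  auto ll_at = [&](int j, int k, double e) {
    return obs_ll(M.family, M.y[j], M.cens[j], e, sig(), M.U, M.horizon,
                  M.leftTrunc);
  };
  auto total_ll = [&]() {
    double s = 0.0;
    for (int j = 0; j < M.nObs; ++j)
      for (int k = 0; k < K; ++k) s += ll_at(j, k, eta[(size_t)j * K + k]);
    return s;
  };

  // proposal scales
  std::vector<double> sBeta(nBeta, 0.1);
  double sSigR = 0.3, sSigG = 0.3, sSigT = 0.3, sGam = 0.2, sThe = 0.5;
  std::vector<int> accBeta(nBeta, 0), tryBeta(nBeta, 0);
  int accSR = 0, trySR = 0, accSG = 0, trySG = 0, accST = 0, tryST = 0;
  int accG = 0, tryG = 0, accT = 0, tryT = 0;

  auto adapt1 = [](double &scale, int &acc, int &tries) {
    if (tries >= 25) {
      double rate = (double)acc / tries;
      scale *= std::exp(1.2 * (rate - 0.3));
      if (scale < 1e-8) scale = 1e-8;
      if (scale > 50) scale = 50;
      acc = 0; tries = 0;
    }
  };

  const int nSave = (nIter - burn + thin - 1) / thin;
  const int nPar = nBeta + (sampleSigmaR ? 1 : 0) + (M.yearIcpt ? 1 : 0) +
    (M.yearSlope ? 1 : 0);
  NumericMatrix draws(nSave, nPar);
  int saved = 0;

  for (int it = 0; it < nIter; ++it) {
    bool adapting = it < adaptUntil;

    // betas: full-likelihood random-walk updates
    for (int b = 0; b < nBeta; ++b) {
      double db = sBeta[b] * norm_rand();
      double nb = beta[b] + db;
      // support / prior
      double lpDelta;
      if (M.family == 1 && b == 0) {
        if (nb <= b0Lower || nb >= b0Upper) { ++tryBeta[b];
          if (adapting) adapt1(sBeta[b], accBeta[b], tryBeta[b]); continue; }
        lpDelta = (beta[b] * beta[b] - nb * nb) / (2.0 * betaVar);
      } else {
        lpDelta = (beta[b] * beta[b] - nb * nb) / (2.0 * betaVar);
      }
      double dll = 0.0;
      if (M.family == 0) {
        for (int j = 0; j < M.nObs; ++j) {
          double de = M.X(j, b) * db;
          for (int k = 0; k < K; ++k) {
            double e0 = eta[(size_t)j * K + k];
            dll += ll_at(j, k, e0 + de) - ll_at(j, k, e0);
          }
        }
      } else {
        for (int j = 0; j < M.nObs; ++j) {
          for (int k = 0; k < K; ++k) {
            double Fi = M.hasINB ? F[(size_t)M.ind[j] * K + k] : 0.0;
            double cov = 1.0;  // covariate multiplying beta[b] for this obs
            if (b > 0) {
              int pos = 1; cov = 0.0;
              if (M.hasINB)   { if (b == pos) cov = Fi;             ++pos; }
              if (M.hasCOL)   { if (b == pos) cov = M.col[j];       ++pos; }
              if (M.hasINT)   { if (b == pos) cov = Fi * M.col[j];  ++pos; }
              if (M.hasFIRST) { if (b == pos) cov = M.first[j];     ++pos; }
            }
            double e0 = eta[(size_t)j * K + k];
            dll += ll_at(j, k, e0 + db * cov) - ll_at(j, k, e0);
          }
        }
      }
      ++tryBeta[b];
      if (std::log(unif_rand()) < dll + lpDelta) {
        beta[b] = nb; ++accBeta[b];
        refresh_eta();
      }
      if (adapting) adapt1(sBeta[b], accBeta[b], tryBeta[b]);
    }

    // sigma (ri residual SD, or gaussian with unknown sigma)
    if (sampleSigmaR) {
      double lns = std::log(sigmaR) + sSigR * norm_rand();
      double ns = std::exp(lns);
      double lp0, lp1;
      if (M.family == 1) {
        lp0 = halfCauchyLog(sigmaR, sigmaRScale);
        lp1 = halfCauchyLog(ns, sigmaRScale);
      } else { // gaussian toy: Unif(0, 100)
        lp0 = (sigmaR > 0 && sigmaR < 100) ? 0.0 : R_NegInf;
        lp1 = (ns > 0 && ns < 100) ? 0.0 : R_NegInf;
      }
      double old = sigmaR;
      double ll0 = total_ll();
      sigmaR = ns;
      double ll1 = total_ll();
      double logr = ll1 - ll0 + lp1 - lp0 + (std::log(ns) - std::log(old));
      ++trySR;
      if (std::log(unif_rand()) < logr) { ++accSR; } else { sigmaR = old; }
      if (adapting) adapt1(sSigR, accSR, trySR);
    }

    // year intercepts gamma (one column per clone)
    if (M.yearIcpt) {
      for (int yy = 0; yy < M.nYears; ++yy) {
        for (int k = 0; k < K; ++k) {
          double dg = sGam * norm_rand();
          double g0 = gamma[(size_t)yy * K + k];
          double dll = 0.0;
          for (int j : obsOfYear[yy]) {
            double e0 = eta[(size_t)j * K + k];
            dll += ll_at(j, k, e0 + dg) - ll_at(j, k, e0);
          }
          double lpD = (g0 * g0 - (g0 + dg) * (g0 + dg)) /
            (2.0 * sigmaG * sigmaG);
          ++tryG;
          if (std::log(unif_rand()) < dll + lpD) {
            gamma[(size_t)yy * K + k] = g0 + dg; ++accG;
            for (int j : obsOfYear[yy]) eta[(size_t)j * K + k] += dg;
          }
        }
      }
      if (adapting) adapt1(sGam, accG, tryG);
      // sigma_gamma
      double lns = std::log(sigmaG) + sSigG * norm_rand();
      double ns = std::exp(lns);
      double lp0, lp1;
      if (sgType == "hc") {
        lp0 = halfCauchyLog(sigmaG, sgScale); lp1 = halfCauchyLog(ns, sgScale);
      } else {
        lp0 = (sigmaG > 0 && sigmaG < sgUpper) ? 0.0 : R_NegInf;
        lp1 = (ns > 0 && ns < sgUpper) ? 0.0 : R_NegInf;
      }
      double dll = 0.0;
      for (int yy = 0; yy < M.nYears; ++yy)
        for (int k = 0; k < K; ++k) {
          double g = gamma[(size_t)yy * K + k];
          dll += R::dnorm(g, 0.0, ns, 1) - R::dnorm(g, 0.0, sigmaG, 1);
        }
      double logr = dll + lp1 - lp0 + (std::log(ns) - std::log(sigmaG));
      ++trySG;
      if (std::log(unif_rand()) < logr) { sigmaG = ns; ++accSG; }
      if (adapting) adapt1(sSigG, accSG, trySG);
    }

    // year slopes theta on F
    if (M.yearSlope) {
      for (int yy = 0; yy < M.nYears; ++yy) {
        for (int k = 0; k < K; ++k) {
          double dt = sThe * norm_rand();
          double t0 = theta[(size_t)yy * K + k];
          double dll = 0.0;
          for (int j : obsOfYear[yy]) {
            double Fi = F[(size_t)M.ind[j] * K + k];
            double e0 = eta[(size_t)j * K + k];
            dll += ll_at(j, k, e0 + dt * Fi) - ll_at(j, k, e0);
          }
          double lpD = (t0 * t0 - (t0 + dt) * (t0 + dt)) /
            (2.0 * sigmaT * sigmaT);
          ++tryT;
          if (std::log(unif_rand()) < dll + lpD) {
            theta[(size_t)yy * K + k] = t0 + dt; ++accT;
            for (int j : obsOfYear[yy]) {
              double Fi = F[(size_t)M.ind[j] * K + k];
              eta[(size_t)j * K + k] += dt * Fi;
            }
          }
        }
      }
      if (adapting) adapt1(sThe, accT, tryT);
      // sigma_theta: Unif(0, upper)
      double lns = std::log(sigmaT) + sSigT * norm_rand();
      double ns = std::exp(lns);
      double lp0 = (sigmaT > 0 && sigmaT < stUpper) ? 0.0 : R_NegInf;
      double lp1 = (ns > 0 && ns < stUpper) ? 0.0 : R_NegInf;
      double dll = 0.0;
      for (int yy = 0; yy < M.nYears; ++yy)
        for (int k = 0; k < K; ++k) {
          double t = theta[(size_t)yy * K + k];
          dll += R::dnorm(t, 0.0, ns, 1) - R::dnorm(t, 0.0, sigmaT, 1);
        }
      double logr = dll + lp1 - lp0 + (std::log(ns) - std::log(sigmaT));
      ++tryST;
      if (std::log(unif_rand()) < logr) { sigmaT = ns; ++accST; }
      if (adapting) adapt1(sSigT, accST, tryST);
    }

    // latent inbreeding coefficients: independence proposal from the
    // Beta(A_i, B_i) measurement prior (prior terms cancel in the ratio)
    if (M.hasINB) {
      for (int i = 0; i < M.nInd; ++i) {
        for (int k = 0; k < K; ++k) {
          double Fp = R::rbeta(M.A[i], M.Bv[i]);
          double F0 = F[(size_t)i * K + k];
          double dll = 0.0;
          for (int j : obsOfInd[i]) {
            double slope = beta[1];
            if (M.yearSlope) slope += theta[(size_t)M.year[j] * K + k];
            int pos = 2 + (M.hasCOL ? 1 : 0);
            double bint = M.hasINT ? beta[pos] : 0.0;
            double de = (slope + bint * M.col[j]) * (Fp - F0);
            double e0 = eta[(size_t)j * K + k];
            dll += ll_at(j, k, e0 + de) - ll_at(j, k, e0);
          }
          if (std::log(unif_rand()) < dll) {
            for (int j : obsOfInd[i]) {
              double slope = beta[1];
              if (M.yearSlope) slope += theta[(size_t)M.year[j] * K + k];
              int pos = 2 + (M.hasCOL ? 1 : 0);
              double bint = M.hasINT ? beta[pos] : 0.0;
              eta[(size_t)j * K + k] += (slope + bint * M.col[j]) * (Fp - F0);
            }
            F[(size_t)i * K + k] = Fp;
          }
        }
      }
    }

    if (it >= burn && ((it - burn) % thin == 0) && saved < nSave) {
      int c = 0;
      for (int b = 0; b < nBeta; ++b) draws(saved, c++) = beta[b];
      if (sampleSigmaR) draws(saved, c++) = sigmaR;
      if (M.yearIcpt) draws(saved, c++) = sigmaG;
      if (M.yearSlope) draws(saved, c++) = sigmaT;
      ++saved;
    }
  }
  return List::create(_["draws"] = draws);
}

// vectorised observation log-likelihood, shared with the R-level reference
// implementations for cross-checking
// [[Rcpp::export]]
NumericVector obs_loglik_cpp(int family, NumericVector y, IntegerVector cens,
                             NumericVector eta, double sigma, double U,
                             double horizon, int leftTrunc) {
  int n = y.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j)
    out[j] = obs_ll(family, y[j], cens[j], eta[j], sigma, U, horizon,
                    leftTrunc);
  return out;
}
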