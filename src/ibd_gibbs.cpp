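#include <Rcpp.h>
using namespace Rcpp;

// One chain of the identity-by-descent Gibbs sampler under data cloning.
//
// Latent structure: per (individual, typed locus) an IBD indicator x; under
// K clones the indicators are iid Bernoulli(q) given (F, p), so their sum
// across clones is drawn as Binomial(K, q) with clone 1 materialised
// explicitly (its per-individual sum of x over loci is the recorded
// "number of loci IBD" statistic). F_i and the allele frequencies p_l are
// structural and shared across clones.
//
// a1, a2: n x L matrices of 1-based allele indices, NA_INTEGER = missing,
//         a1 <= a2. nAlleles: registry size per locus.
// Returns saved draws of F (nsave x n) and the clone-1 IBD count k
// (nsave x n).
// [[Rcpp::export]]
List ibd_gibbs_chain(IntegerMatrix a1, IntegerMatrix a2,
                     IntegerVector nAlleles, int K,
                     int nIter, int burnIn, int thin,
                     double aPrior, double bPrior,
                     double flo, double cei) {
  const int n = a1.nrow(), L = a1.ncol();

  // typed-locus counts and homozygous-call index
  std::vector<int> Li(n, 0);
  std::vector<int> homI, homL, homM;
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      if (a1(i, l) == NA_INTEGER) continue;
      Li[i] += 1;
      if (a1(i, l) == a2(i, l)) {
        homI.push_back(i); homL.push_back(l); homM.push_back(a1(i, l) - 1);
      }
    }
  const int nHom = (int)homI.size();

  // per-clone heterozygote contributions to Z (1 per allele state)
  std::vector< std::vector<double> > hetZ(L);
  for (int l = 0; l < L; ++l) hetZ[l].assign(nAlleles[l], 0.0);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      if (a1(i, l) == NA_INTEGER || a1(i, l) == a2(i, l)) continue;
      hetZ[l][a1(i, l) - 1] += 1.0;
      hetZ[l][a2(i, l) - 1] += 1.0;
    }

  // state
  std::vector<double> F(n);
  for (int i = 0; i < n; ++i) F[i] = R::rbeta(aPrior, bPrior);
  std::vector< std::vector<double> > p(L);
  for (int l = 0; l < L; ++l)
    p[l].assign(nAlleles[l], 1.0 / nAlleles[l]);
  std::vector<int> s(nHom, 0);   // clone-summed x per homozygous call
  std::vector<int> x1(nHom, 0);  // clone-1 indicator

  const int nSave = (nIter - burnIn + thin - 1) / thin;
  NumericMatrix Fdraws(nSave, n);
  IntegerMatrix kdraws(nSave, n);
  int saved = 0;

  std::vector<double> sumS(n);

  for (int it = 0; it < nIter; ++it) {
    // x | F, p
    for (int j = 0; j < nHom; ++j) {
      double Ft = F[homI[j]];
      if (Ft < flo) Ft = flo; else if (Ft > cei) Ft = cei;
      double pm = p[homL[j]][homM[j]];
      double q = Ft * pm / (Ft * pm + (1.0 - Ft) * pm * pm);
      x1[j] = (unif_rand() < q) ? 1 : 0;
      s[j] = x1[j] + (K > 1 ? (int)R::rbinom(K - 1, q) : 0);
    }
    // F | x (conjugate Beta update on the clone-summed counts)
    std::fill(sumS.begin(), sumS.end(), 0.0);
    for (int j = 0; j < nHom; ++j) sumS[homI[j]] += s[j];
    for (int i = 0; i < n; ++i)
      F[i] = R::rbeta(aPrior + sumS[i],
                      bPrior + (double)K * Li[i] - sumS[i]);
    // Z | x, genotypes, then p | Z ~ Dirichlet(1 + Z)
    {
      std::vector< std::vector<double> > Z(L);
      for (int l = 0; l < L; ++l) {
        Z[l].assign(nAlleles[l], 0.0);
        for (int m = 0; m < nAlleles[l]; ++m) Z[l][m] = K * hetZ[l][m];
      }
      for (int j = 0; j < nHom; ++j)
        Z[homL[j]][homM[j]] += 2.0 * K - s[j];
      for (int l = 0; l < L; ++l) {
        double tot = 0.0;
        for (int m = 0; m < nAlleles[l]; ++m) {
          double g = R::rgamma(1.0 + Z[l][m], 1.0);
          p[l][m] = g; tot += g;
        }
        for (int m = 0; m < nAlleles[l]; ++m) p[l][m] /= tot;
      }
    }
    // save
    if (it >= burnIn && ((it - burnIn) % thin == 0) && saved < nSave) {
      std::vector<int> k1(n, 0);
      for (int j = 0; j < nHom; ++j) k1[homI[j]] += x1[j];
      for (int i = 0; i < n; ++i) {
        Fdraws(saved, i) = F[i];
        kdraws(saved, i) = k1[i];
      }
      ++saved;
    }
  }
  return List::create(_["F"] = Fdraws, _["k"] = kdraws,
                      _["typed"] = wrap(Li));
}
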