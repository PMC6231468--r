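#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured coalescent under a piecewise-constant multi-deme demography.
//
// Demography encoding (built by demog_epochs() on the R side):
//   - K demes; E merge events at strictly increasing times (generations).
//   - sizes:  (E+1) x K matrix of diploid deme sizes, row e = epoch e.
//   - mig:    flat array of length (E+1)*K*K; mig[e*K*K + i*K + j] is the
//             per-generation probability that a lineage currently in deme i
//             traces back to deme j (backward migration rate).
//   - At event e all lineages in deme src[e] move to deme dst[e]; epoch e+1
//     rates/sizes then apply.  Rates involving dead demes must be zero.
//
// Rates: pairwise coalescence within deme d at 1/(2N_d) per generation,
// lineage migration i->j at mig_ij.  Time is continuous, in generations.

struct Demog {
  int K, E;
  const double *etimes;
  const int *esrc, *edst;
  const double *sizes; // (E+1) x K column-major from R: sizes[e + (E+1)*d]
  const double *mig;   // e*K*K + i*K + j
  int nrow_sizes;
};

struct Genealogy {
  int n;                    // leaves
  std::vector<double> time; // 2n-1 node times
  std::vector<int> child1, child2;
  std::vector<int> cnt;     // (2n-1) x K leaf counts per deme, node-major
  std::vector<int> bnode;   // finalized branches (all but root)
  std::vector<double> blen;
  double totlen, tmrca;
};

// simulate one genealogy; returns false on event-cap blowup
static bool sim_one(const Demog &D, const std::vector<int> &n_per_deme,
                    Genealogy &G) {
  const int K = D.K;
  int n = 0;
  for (int d = 0; d < K; ++d) n += n_per_deme[d];
  const int ntot = 2 * n - 1;
  G.n = n;
  G.time.assign(ntot, 0.0);
  G.child1.assign(ntot, -1);
  G.child2.assign(ntot, -1);
  G.cnt.assign((size_t)ntot * K, 0);
  G.bnode.clear(); G.blen.clear();
  G.bnode.reserve(ntot - 1); G.blen.reserve(ntot - 1);
  G.totlen = 0.0;

  std::vector<std::vector<int> > deme(K);
  int id = 0;
  for (int d = 0; d < K; ++d)
    for (int i = 0; i < n_per_deme[d]; ++i) {
      deme[d].push_back(id);
      G.cnt[(size_t)id * K + d] = 1;
      ++id;
    }
  int nxt = n, k_tot = n, epoch = 0;
  double t = 0.0;
  const double cap = 2e5; // event safety cap (legitimate genealogies need ~1e2-1e3)
  double nev = 0.0;

  std::vector<double> crate(K), mrate(K);
  while (k_tot > 1) {
    double R = 0.0;
    for (int d = 0; d < K; ++d) {
      const double kd = (double)deme[d].size();
      const double N = D.sizes[epoch + D.nrow_sizes * d];
      crate[d] = kd > 1.5 ? kd * (kd - 1.0) * 0.5 / (2.0 * N) : 0.0;
      double mrow = 0.0;
      const double *mg = D.mig + (size_t)epoch * K * K + (size_t)d * K;
      for (int j = 0; j < K; ++j) mrow += mg[j];
      mrate[d] = kd * mrow;
      R += crate[d] + mrate[d];
    }
    if (R <= 0.0) {
      if (epoch >= D.E) return false; // stuck: no events possible
      t = D.etimes[epoch];
      const int s = D.esrc[epoch], q = D.edst[epoch];
      for (size_t i = 0; i < deme[s].size(); ++i) deme[q].push_back(deme[s][i]);
      deme[s].clear();
      ++epoch;
      continue;
    }
    const double dt = exp_rand() / R;
    if (epoch < D.E && t + dt >= D.etimes[epoch]) {
      t = D.etimes[epoch];
      const int s = D.esrc[epoch], q = D.edst[epoch];
      for (size_t i = 0; i < deme[s].size(); ++i) deme[q].push_back(deme[s][i]);
      deme[s].clear();
      ++epoch;
      continue;
    }
    t += dt;
    if (++nev > cap) return false;
    double u = unif_rand() * R;
    int d = 0;
    bool coal = false;
    for (; d < K; ++d) {
      if (u < crate[d]) { coal = true; break; }
      u -= crate[d];
      if (u < mrate[d]) break;
      u -= mrate[d];
    }
    if (d >= K) d = K - 1; // numeric guard: treat as last deme migration
    if (coal) {
      std::vector<int> &L = deme[d];
      const int kd = (int)L.size();
      int i = (int)(unif_rand() * kd); if (i >= kd) i = kd - 1;
      int j = (int)(unif_rand() * (kd - 1)); if (j >= kd - 1) j = kd - 2;
      if (j >= i) ++j;
      const int a = L[i], b = L[j];
      const int v = nxt++;
      G.time[v] = t;
      G.child1[v] = a; G.child2[v] = b;
      int *cv = &G.cnt[(size_t)v * K];
      const int *ca = &G.cnt[(size_t)a * K], *cb = &G.cnt[(size_t)b * K];
      for (int x = 0; x < K; ++x) cv[x] = ca[x] + cb[x];
      const double la = t - G.time[a], lb = t - G.time[b];
      G.bnode.push_back(a); G.blen.push_back(la);
      G.bnode.push_back(b); G.blen.push_back(lb);
      G.totlen += la + lb;
      // remove a,b (i,j), push v
      if (i > j) { int tmp = i; i = j; j = tmp; }
      L[j] = L.back(); L.pop_back();
      L[i] = L.back(); L.pop_back();
      L.push_back(v);
      --k_tot;
    } else {
      std::vector<int> &L = deme[d];
      const int kd = (int)L.size();
      if (kd == 0) continue; // FP fallthrough onto an empty deme: no-op
      int i = (int)(unif_rand() * kd); if (i >= kd) i = kd - 1;
      // u is residual within mrate[d] = kd * mrow
      double w = u / (double)kd;
      const double *mg = D.mig + (size_t)epoch * K * K + (size_t)d * K;
      int j = 0;
      for (; j < K - 1; ++j) {
        if (w < mg[j]) break;
        w -= mg[j];
      }
      const int lin = L[i];
      L[i] = L.back(); L.pop_back();
      deme[j].push_back(lin);
    }
  }
  // root = remaining lineage
  int root = -1;
  for (int d = 0; d < K; ++d)
    if (!deme[d].empty()) { root = deme[d][0]; break; }
  G.tmrca = G.time[root];
  return true;
}

static Demog make_demog(const IntegerVector &n_per_deme,
                        const NumericVector &event_times,
                        const IntegerVector &event_src,
                        const IntegerVector &event_dst,
                        const NumericMatrix &sizes, const NumericVector &mig) {
  Demog D;
  D.K = n_per_deme.size();
  D.E = event_times.size();
  D.etimes = event_times.begin();
  D.esrc = event_src.begin();
  D.edst = event_dst.begin();
  D.sizes = sizes.begin();
  D.nrow_sizes = sizes.nrow();
  D.mig = mig.begin();
  if (sizes.nrow() != D.E + 1 || sizes.ncol() != D.K)
    stop("sizes must be (n_events+1) x n_demes");
  if ((int)mig.size() != (D.E + 1) * D.K * D.K)
    stop("mig must have length (n_events+1)*K*K");
  return D;
}

static std::vector<int> as_std(const IntegerVector &v) {
  return std::vector<int>(v.begin(), v.end());
}

// A random SNP comes from a genealogy with probability proportional to its
// total branch length (longer trees carry more mutations).  Rejection
// sampler with an adaptive bound; trees exceeding the bound are accepted
// and raise it (the overshoot mass is negligible for the exponential-tailed
// length distribution).
static bool sim_one_length_weighted(const Demog &D,
                                    const std::vector<int> &npd,
                                    Genealogy &G, double &bound) {
  if (bound <= 0.0) { // warm-up: calibrate the bound
    double mx = 0.0;
    for (int w = 0; w < 100; ++w) {
      if (!sim_one(D, npd, G)) return false;
      if (G.totlen > mx) mx = G.totlen;
    }
    bound = 2.0 * mx;
  }
  for (int tries = 0; tries < 1000000; ++tries) {
    if (!sim_one(D, npd, G)) return false;
    if (G.totlen >= bound) { bound = 1.5 * G.totlen; return true; }
    if (unif_rand() < G.totlen / bound) return true;
  }
  return false;
}

// Branch-length-weighted joint SFS: for every deme pair (a<b) accumulate the
// expected length carrying each derived-count configuration (i in pop a,
// j in pop b), summed over n_sims independent genealogies.  Mutations being
// uniform on branches, entry (i,j) / total is the probability that a SNP
// (polymorphic in the pooled sample) shows that unfolded configuration.
// [[Rcpp::export]]
List sim_pair_sfs_branch_cpp(IntegerVector n_per_deme, NumericVector event_times,
                             IntegerVector event_src, IntegerVector event_dst,
                             NumericMatrix sizes, NumericVector mig, int n_sims) {
  Demog D = make_demog(n_per_deme, event_times, event_src, event_dst, sizes, mig);
  const int K = D.K;
  std::vector<int> npd = as_std(n_per_deme);
  std::vector<int> pa, pb;
  for (int a = 0; a < K; ++a)
    for (int b = a + 1; b < K; ++b) { pa.push_back(a); pb.push_back(b); }
  const int P = (int)pa.size();
  std::vector<NumericMatrix> mats;
  for (int p = 0; p < P; ++p)
    mats.push_back(NumericMatrix(npd[pa[p]] + 1, npd[pb[p]] + 1));
  List marg(K);
  std::vector<double *> margp(K);
  for (int d = 0; d < K; ++d) {
    NumericVector m(npd[d] + 1);
    marg[d] = m;
    margp[d] = REAL(m);
  }
  Genealogy G;
  double tot = 0.0;
  int failed = 0;
  for (int s = 0; s < n_sims; ++s) {
    if (!sim_one(D, npd, G)) { ++failed; continue; }
    tot += G.totlen;
    const int nb = (int)G.bnode.size();
    for (int e = 0; e < nb; ++e) {
      const int *c = &G.cnt[(size_t)G.bnode[e] * K];
      const double l = G.blen[e];
      for (int p = 0; p < P; ++p)
        mats[p](c[pa[p]], c[pb[p]]) += l;
      for (int d = 0; d < K; ++d) margp[d][c[d]] += l;
    }
  }
  List pl(P);
  IntegerVector ra(P), rb(P);
  for (int p = 0; p < P; ++p) { pl[p] = mats[p]; ra[p] = pa[p] + 1; rb[p] = pb[p] + 1; }
  return List::create(_["pairs"] = pl, _["pair_a"] = ra, _["pair_b"] = rb,
                      _["marginal"] = marg, _["total_length"] = tot,
                      _["n_failed"] = failed);
}

// One SNP per genealogy: sample a branch with probability proportional to its
// length and report the derived-allele count in each deme.
// [[Rcpp::export]]
IntegerMatrix sim_snp_configs_cpp(IntegerVector n_per_deme, NumericVector event_times,
                                  IntegerVector event_src, IntegerVector event_dst,
                                  NumericMatrix sizes, NumericVector mig, int n_snps) {
  Demog D = make_demog(n_per_deme, event_times, event_src, event_dst, sizes, mig);
  const int K = D.K;
  std::vector<int> npd = as_std(n_per_deme);
  IntegerMatrix out(n_snps, K);
  Genealogy G;
  double bound = 0.0;
  for (int s = 0; s < n_snps; ++s) {
    if (!sim_one_length_weighted(D, npd, G, bound))
      stop("simulation event cap exceeded");
    double u = unif_rand() * G.totlen, acc = 0.0;
    int pick = G.bnode.back();
    for (size_t e = 0; e < G.bnode.size(); ++e) {
      acc += G.blen[e];
      if (u < acc) { pick = G.bnode[e]; break; }
    }
    const int *c = &G.cnt[(size_t)pick * K];
    for (int d = 0; d < K; ++d) out(s, d) = c[d];
  }
  return out;
}

static void mark_leaves(const Genealogy &G, int v, std::vector<int> &stack,
                        int *col) {
  stack.clear();
  stack.push_back(v);
  while (!stack.empty()) {
    const int x = stack.back();
    stack.pop_back();
    if (G.child1[x] < 0) col[x] = 1;
    else { stack.push_back(G.child1[x]); stack.push_back(G.child2[x]); }
  }
}

// GBS-style loci: one genealogy per locus, snps_per_locus mutations placed on
// branches chosen proportional to length (each SNP polymorphic in the pooled
// sample).  Rows are haplotypes in deme-block order; 0/1 carrier states.
// [[Rcpp::export]]
IntegerMatrix sim_haplotypes_cpp(IntegerVector n_per_deme, NumericVector event_times,
                                 IntegerVector event_src, IntegerVector event_dst,
                                 NumericMatrix sizes, NumericVector mig,
                                 int n_loci, int snps_per_locus) {
  Demog D = make_demog(n_per_deme, event_times, event_src, event_dst, sizes, mig);
  std::vector<int> npd = as_std(n_per_deme);
  int n = 0;
  for (size_t d = 0; d < npd.size(); ++d) n += npd[d];
  IntegerMatrix out(n, n_loci * snps_per_locus);
  Genealogy G;
  std::vector<int> stack;
  std::vector<int> carrier(2 * n - 1);
  double bound = 0.0;
  for (int l = 0; l < n_loci; ++l) {
    if (!sim_one_length_weighted(D, npd, G, bound))
      stop("simulation event cap exceeded");
    for (int s = 0; s < snps_per_locus; ++s) {
      double u = unif_rand() * G.totlen, acc = 0.0;
      int pick = G.bnode.back();
      for (size_t e = 0; e < G.bnode.size(); ++e) {
        acc += G.blen[e];
        if (u < acc) { pick = G.bnode[e]; break; }
      }
      std::fill(carrier.begin(), carrier.end(), 0);
      mark_leaves(G, pick, stack, carrier.data());
      const int col = l * snps_per_locus + s;
      for (int i = 0; i < n; ++i) out(i, col) = carrier[i];
    }
  }
  return out;
}

// Finite-locus sequence mode: per locus of L sites, mutation count is
// Poisson(total_length * mu * L); each mutation hits a uniform site on a
// branch chosen proportional to length (carriers flip, so recurrent
// mutation at a site is possible but rare for mu*L << 1/totlen).
// [[Rcpp::export]]
IntegerMatrix sim_sequences_cpp(IntegerVector n_per_deme, NumericVector event_times,
                                IntegerVector event_src, IntegerVector event_dst,
                                NumericMatrix sizes, NumericVector mig,
                                int n_loci, int L, double mu) {
  Demog D = make_demog(n_per_deme, event_times, event_src, event_dst, sizes, mig);
  std::vector<int> npd = as_std(n_per_deme);
  int n = 0;
  for (size_t d = 0; d < npd.size(); ++d) n += npd[d];
  IntegerMatrix out(n, n_loci * L);
  Genealogy G;
  std::vector<int> stack;
  std::vector<int> carrier(2 * n - 1);
  for (int l = 0; l < n_loci; ++l) {
    if (!sim_one(D, npd, G)) stop("simulation event cap exceeded");
    const int nmut = (int)R::rpois(G.totlen * mu * (double)L);
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * G.totlen, acc = 0.0;
      int pick = G.bnode.back();
      for (size_t e = 0; e < G.bnode.size(); ++e) {
        acc += G.blen[e];
        if (u < acc) { pick = G.bnode[e]; break; }
      }
      int site = (int)(unif_rand() * L); if (site >= L) site = L - 1;
      std::fill(carrier.begin(), carrier.end(), 0);
      mark_leaves(G, pick, stack, carrier.data());
      const int col = l * L + site;
      for (int i = 0; i < n; ++i)
        if (carrier[i]) out(i, col) = 1 - out(i, col);
    }
  }
  return out;
}

// TMRCA and total branch length per replicate genealogy.
// [[Rcpp::export]]
NumericMatrix sim_tmrca_cpp(IntegerVector n_per_deme, NumericVector event_times,
                            IntegerVector event_src, IntegerVector event_dst,
                            NumericMatrix sizes, NumericVector mig, int n_reps) {
  Demog D = make_demog(n_per_deme, event_times, event_src, event_dst, sizes, mig);
  std::vector<int> npd = as_std(n_per_deme);
  NumericMatrix out(n_reps, 2);
  colnames(out) = CharacterVector::create("tmrca", "total_length");
  Genealogy G;
  for (int s = 0; s < n_reps; ++s) {
    if (!sim_one(D, npd, G)) stop("simulation event cap exceeded");
    out(s, 0) = G.tmrca;
    out(s, 1) = G.totlen;
  }
  return out;
}

// One genealogy, full topology (for conversion to an ape phylo on the R side).
// [[Rcpp::export]]
List sim_tree_cpp(IntegerVector n_per_deme, NumericVector event_times,
                  IntegerVector event_src, IntegerVector event_dst,
                  NumericMatrix sizes, NumericVector mig) {
  Demog D = make_demog(n_per_deme, event_times, event_src, event_dst, sizes, mig);
  std::vector<int> npd = as_std(n_per_deme);
  Genealogy G;
  if (!sim_one(D, npd, G)) stop("simulation event cap exceeded");
  const int ntot = 2 * G.n - 1;
  IntegerVector c1(ntot), c2(ntot);
  NumericVector tm(ntot);
  for (int i = 0; i < ntot; ++i) {
    c1[i] = G.child1[i] + 1; // 0 for leaves
    c2[i] = G.child2[i] + 1;
    tm[i] = G.time[i];
  }
  return List::create(_["n_leaves"] = G.n, _["child1"] = c1, _["child2"] = c2,
                      _["time"] = tm, _["tmrca"] = G.tmrca,
                      _["total_length"] = G.totlen);
}
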