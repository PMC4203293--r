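#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Structured coalescent with instantaneous merge events.
//
// Time runs pastward in generations from 0. Within each extant branch
// (group) g holding k lineages, a pair coalesces at rate k(k-1)/2 / (2 N_g x)
// where x is the inheritance scalar (0.25 mtDNA, 1 autosomal). At each event
// all lineages of `from` move into `to`; `to` may take a new effective size.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List coal_tree_cpp(IntegerVector tips_per_group,
                   NumericVector group_N,
                   double x,
                   NumericVector event_time,
                   IntegerVector event_from,
                   IntegerVector event_to,
                   NumericVector event_newN) {
  int G = tips_per_group.size();
  int ntip = 0;
  for (int g = 0; g < G; ++g) ntip += tips_per_group[g];
  if (ntip < 2) stop("need at least two lineages in total");
  int nnode = 2 * ntip - 1;
  IntegerVector parent(nnode, -1);
  NumericVector ntime(nnode, 0.0);
  IntegerVector tipgroup(ntip);
  std::vector< std::vector<int> > active(G);
  std::vector<double> N(group_N.begin(), group_N.end());
  int id = 0;
  for (int g = 0; g < G; ++g) {
    for (int i = 0; i < tips_per_group[g]; ++i) {
      active[g].push_back(id);
      tipgroup[id] = g;
      ++id;
    }
  }
  int nextnode = ntip;
  double t = 0.0;
  int ev = 0, nev = event_time.size();
  int nact = ntip;
  while (nact > 1) {
    double best = R_PosInf;
    int bg = -1;
    for (int g = 0; g < G; ++g) {
      int k = (int) active[g].size();
      if (k < 2) continue;
      if (N[g] <= 0.0) stop("effective size must be positive");
      double rate = 0.5 * k * (k - 1.0) / (2.0 * N[g] * x);
      double w = R::exp_rand() / rate;
      if (w < best) { best = w; bg = g; }
    }
    double tnext = t + best;
    if (ev < nev && event_time[ev] < tnext) {
      t = event_time[ev];
      int from = event_from[ev], to = event_to[ev];
      for (size_t i = 0; i < active[from].size(); ++i)
        active[to].push_back(active[from][i]);
      active[from].clear();
      if (event_newN[ev] > 0.0) N[to] = event_newN[ev];
      ++ev;
      continue;
    }
    if (bg < 0) stop("remaining lineages can never coalesce: check merge events");
    t = tnext;
    int k = (int) active[bg].size();
    int i = (int) (unif_rand() * k); if (i == k) i = k - 1;
    int j = (int) (unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[bg][i], b = active[bg][j];
    int p = nextnode++;
    parent[a] = p; parent[b] = p;
    ntime[p] = t;
    if (i < j) std::swap(i, j);
    active[bg][i] = active[bg].back(); active[bg].pop_back();
    active[bg][j] = active[bg].back(); active[bg].pop_back();
    active[bg].push_back(p);
    --nact;
  }
  return List::create(_["parent"] = parent, _["time"] = ntime,
                      _["tip_group"] = tipgroup, _["n_tip"] = ntip);
}

// Finite-site mutation along a coalescent tree. Mutations fall as a Poisson
// process (rate mu_site_gen per site per generation); each event substitutes
// the current base through a two-parameter kernel: transition with
// probability kappa/(kappa+2), otherwise one of the two transversions.
// Root sequence drawn uniform over {A,C,G,T}. Returns tip sequences as a
// raw matrix of ASCII bytes (rows = tips).
// [[Rcpp::export]]
RawMatrix mutate_sequence_cpp(IntegerVector parent, NumericVector ntime,
                              int ntip, int L, double mu_site_gen,
                              double kappa) {
  if (mu_site_gen < 0.0) stop("mutation rate must be non-negative");
  int nnode = parent.size();
  std::vector< std::vector<int> > child(nnode);
  int root = -1;
  for (int i = 0; i < nnode; ++i) {
    if (parent[i] < 0) root = i; else child[parent[i]].push_back(i);
  }
  // bases coded 0=A 1=C 2=G 3=T; transition flips bit 2 (A<->G, C<->T),
  // transversions flip the purine/pyrimidine class (xor 1 or xor 3)
  std::vector<uint8_t> seq((size_t) nnode * L);
  for (int s = 0; s < L; ++s) {
    int b = (int) (unif_rand() * 4.0); if (b == 4) b = 3;
    seq[(size_t) root * L + s] = (uint8_t) b;
  }
  double ptrans = kappa / (kappa + 2.0);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int node = stack.back(); stack.pop_back();
    if (node != root) {
      int p = parent[node];
      std::memcpy(&seq[(size_t) node * L], &seq[(size_t) p * L], L);
      double blen = ntime[p] - ntime[node];
      int m = (int) R::rpois(blen * mu_site_gen * L);
      for (int mm = 0; mm < m; ++mm) {
        int s = (int) (unif_rand() * L); if (s == L) s = L - 1;
        uint8_t b = seq[(size_t) node * L + s];
        uint8_t nb;
        if (unif_rand() < ptrans) {
          nb = b ^ 2;
        } else {
          nb = (unif_rand() < 0.5) ? (uint8_t) (b ^ 1) : (uint8_t) (b ^ 3);
        }
        seq[(size_t) node * L + s] = nb;
      }
    }
    for (size_t c = 0; c < child[node].size(); ++c) stack.push_back(child[node][c]);
  }
  static const unsigned char letter[4] = {'A', 'C', 'G', 'T'};
  RawMatrix out(ntip, L);
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < L; ++s)
      out(i, s) = letter[seq[(size_t) i * L + s]];
  return out;
}

// Generalized stepwise mutation along a coalescent tree: each mutation moves
// the allele size by +/- (1 + Geometric(P)); P = 0 is the strict single-step
// model. Returns tip allele sizes (repeat units).
// [[Rcpp::export]]
IntegerVector mutate_microsat_cpp(IntegerVector parent, NumericVector ntime,
                                  int ntip, double mu_gen, double gsm_p,
                                  int root_size) {
  if (mu_gen < 0.0) stop("mutation rate must be non-negative");
  if (gsm_p < 0.0 || gsm_p >= 1.0) stop("GSM parameter must be in [0, 1)");
  int nnode = parent.size();
  std::vector< std::vector<int> > child(nnode);
  int root = -1;
  for (int i = 0; i < nnode; ++i) {
    if (parent[i] < 0) root = i; else child[parent[i]].push_back(i);
  }
  std::vector<int> val(nnode, root_size);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int node = stack.back(); stack.pop_back();
    if (node != root) {
      int p = parent[node];
      int v = val[p];
      double blen = ntime[p] - ntime[node];
      int m = (int) R::rpois(blen * mu_gen);
      for (int mm = 0; mm < m; ++mm) {
        int step = 1;
        if (gsm_p > 0.0) step += (int) R::rgeom(1.0 - gsm_p);
        v += (unif_rand() < 0.5) ? -step : step;
      }
      val[node] = v;
    }
    for (size_t c = 0; c < child[node].size(); ++c) stack.push_back(child[node][c]);
  }
  IntegerVector out(ntip);
  for (int i = 0; i < ntip; ++i) out[i] = val[i];
  return out;
}

// Pairwise Hamming differences over the segregating columns of an alignment
// held as a raw byte matrix (rows = sequences). Also returns the 1-based
// indices of segregating columns.
// [[Rcpp::export]]
List seq_pairdiff_cpp(RawMatrix seqs) {
  int n = seqs.nrow(), L = seqs.ncol();
  std::vector<int> varcols;
  for (int s = 0; s < L; ++s) {
    Rbyte b = seqs(0, s);
    for (int i = 1; i < n; ++i) {
      if (seqs(i, s) != b) { varcols.push_back(s); break; }
    }
  }
  int S = (int) varcols.size();
  // copy the segregating columns into a compact row-major buffer
  std::vector<uint8_t> buf((size_t) n * S);
  for (int k = 0; k < S; ++k) {
    int s = varcols[k];
    for (int i = 0; i < n; ++i) buf[(size_t) i * S + k] = seqs(i, s);
  }
  NumericMatrix d(n, n);
  if (S > 0) {
    const uint8_t* base = buf.data();
    for (int i = 0; i < n; ++i) {
      const uint8_t* ri = base + (size_t) i * S;
      for (int j = i + 1; j < n; ++j) {
        const uint8_t* rj = base + (size_t) j * S;
        int c = 0;
        for (int k = 0; k < S; ++k) c += (ri[k] != rj[k]);
        d(i, j) = c; d(j, i) = c;
      }
    }
  }
  IntegerVector vc(S);
  for (int k = 0; k < S; ++k) vc[k] = varcols[k] + 1;
  return List::create(_["d"] = d, _["varsites"] = vc);
}

// Registry microsatellite statistics for the three analysis groups.
// a1, a2: individuals x loci allele-size matrices (NA = missing);
// group: 0-based group index per individual. Returns the per-group means
// over usable loci of (allele count, unbiased He, allele-size variance),
// the per-pair multilocus Weir-Cockerham theta (ratio of sums over loci
// and alleles) and the per-pair Goldstein (delta mu)^2 mean squared
// allele-size difference, pairs ordered (0,1), (0,2), (1,2).
// [[Rcpp::export]]
List msat_sumstats_cpp(IntegerMatrix a1, IntegerMatrix a2,
                       IntegerVector group, int ngroups) {
  int nind = a1.nrow(), nloc = a1.ncol();
  NumericMatrix pg(ngroups, 3);
  IntegerVector used(ngroups);
  int npair = ngroups * (ngroups - 1) / 2;
  NumericVector suma(npair), sumabc(npair);
  NumericVector dmu2(npair);
  IntegerVector dmu2_nloc(npair);
  std::vector<double> gmean(ngroups);
  std::vector<bool> gmean_ok(ngroups);
  std::vector< std::vector<int> > members(ngroups);
  for (int i = 0; i < nind; ++i) members[group[i]].push_back(i);
  std::vector<int> copies, alleles;
  for (int l = 0; l < nloc; ++l) {
    for (int g = 0; g < ngroups; ++g) { gmean[g] = 0.0; gmean_ok[g] = false; }
    // per-group one-sample statistics
    for (int g = 0; g < ngroups; ++g) {
      copies.clear();
      for (size_t mi = 0; mi < members[g].size(); ++mi) {
        int i = members[g][mi];
        if (a1(i, l) != NA_INTEGER) copies.push_back(a1(i, l));
        if (a2(i, l) != NA_INTEGER) copies.push_back(a2(i, l));
      }
      int n = (int) copies.size();
      if (n < 1) continue;
      double sum = 0.0, sumsq = 0.0, sump2 = 0.0;
      for (int i = 0; i < n; ++i) { sum += copies[i]; sumsq += copies[i] * (double) copies[i]; }
      gmean[g] = sum / n;
      gmean_ok[g] = true;
      if (n < 2) continue;
      std::sort(copies.begin(), copies.end());
      int A = 0;
      for (int i = 0; i < n; ) {
        int j = i;
        while (j < n && copies[j] == copies[i]) ++j;
        double p = (double) (j - i) / n;
        sump2 += p * p;
        ++A;
        i = j;
      }
      double he = n * (1.0 - sump2) / (n - 1.0);
      double v = (sumsq - sum * sum / n) / (n - 1.0);
      pg(g, 0) += A;
      pg(g, 1) += he;
      pg(g, 2) += v;
      ++used[g];
    }
    // per-pair (delta mu)^2 from the per-group mean allele sizes
    {
      int pidx = 0;
      for (int g1 = 0; g1 < ngroups; ++g1) {
        for (int g2 = g1 + 1; g2 < ngroups; ++g2, ++pidx) {
          if (gmean_ok[g1] && gmean_ok[g2]) {
            double dd = gmean[g1] - gmean[g2];
            dmu2[pidx] += dd * dd;
            ++dmu2_nloc[pidx];
          }
        }
      }
    }
    // per-pair Weir-Cockerham components
    int pidx = 0;
    for (int g1 = 0; g1 < ngroups; ++g1) {
      for (int g2 = g1 + 1; g2 < ngroups; ++g2, ++pidx) {
        std::vector<int> c1a, c1b, c2a, c2b;
        for (size_t mi = 0; mi < members[g1].size(); ++mi) {
          int i = members[g1][mi];
          if (a1(i, l) != NA_INTEGER && a2(i, l) != NA_INTEGER) {
            c1a.push_back(a1(i, l)); c1b.push_back(a2(i, l));
          }
        }
        for (size_t mi = 0; mi < members[g2].size(); ++mi) {
          int i = members[g2][mi];
          if (a1(i, l) != NA_INTEGER && a2(i, l) != NA_INTEGER) {
            c2a.push_back(a1(i, l)); c2b.push_back(a2(i, l));
          }
        }
        int n1 = (int) c1a.size(), n2 = (int) c2a.size();
        if (n1 < 1 || n2 < 1) continue;
        double nbar = (n1 + n2) / 2.0;
        if (nbar <= 1.0) continue;
        double r = 2.0;
        double nc = (n1 + n2 - (n1 * (double) n1 + n2 * (double) n2) /
                     (n1 + n2)) / (r - 1.0);
        alleles.clear();
        alleles.insert(alleles.end(), c1a.begin(), c1a.end());
        alleles.insert(alleles.end(), c1b.begin(), c1b.end());
        alleles.insert(alleles.end(), c2a.begin(), c2a.end());
        alleles.insert(alleles.end(), c2b.begin(), c2b.end());
        std::sort(alleles.begin(), alleles.end());
        alleles.erase(std::unique(alleles.begin(), alleles.end()),
                      alleles.end());
        for (size_t ai = 0; ai < alleles.size(); ++ai) {
          int al = alleles[ai];
          int cnt1 = 0, het1 = 0, cnt2 = 0, het2 = 0;
          for (int i = 0; i < n1; ++i) {
            bool x = c1a[i] == al, y = c1b[i] == al;
            cnt1 += x + y;
            het1 += (x != y);
          }
          for (int i = 0; i < n2; ++i) {
            bool x = c2a[i] == al, y = c2b[i] == al;
            cnt2 += x + y;
            het2 += (x != y);
          }
          double p1 = cnt1 / (2.0 * n1), p2 = cnt2 / (2.0 * n2);
          double h1 = (double) het1 / n1, h2 = (double) het2 / n2;
          double pbar = (n1 * p1 + n2 * p2) / (n1 + n2);
          double s2 = (n1 * (p1 - pbar) * (p1 - pbar) +
                       n2 * (p2 - pbar) * (p2 - pbar)) / ((r - 1.0) * nbar);
          double hbar = (n1 * h1 + n2 * h2) / (double) (n1 + n2);
          double a = (nbar / nc) *
            (s2 - (pbar * (1.0 - pbar) - ((r - 1.0) / r) * s2 - hbar / 4.0) /
             (nbar - 1.0));
          double b = (nbar / (nbar - 1.0)) *
            (pbar * (1.0 - pbar) - ((r - 1.0) / r) * s2 -
             ((2.0 * nbar - 1.0) / (4.0 * nbar)) * hbar);
          double cterm = hbar / 2.0;
          suma[pidx] += a;
          sumabc[pidx] += a + b + cterm;
        }
      }
    }
  }
  for (int g = 0; g < ngroups; ++g) {
    for (int s = 0; s < 3; ++s)
      pg(g, s) = used[g] > 0 ? pg(g, s) / used[g] : NA_REAL;
  }
  NumericVector fst(npair);
  for (int p = 0; p < npair; ++p) {
    fst[p] = sumabc[p] > 0.0 ? suma[p] / sumabc[p] : 0.0;
    dmu2[p] = dmu2_nloc[p] > 0 ? dmu2[p] / dmu2_nloc[p] : NA_REAL;
  }
  return List::create(_["per_group"] = pg, _["fst"] = fst,
                      _["dmu2"] = dmu2);
}
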