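// Geometry kernels: Kabsch superposition, TM-score rotation search,
// iterative structural alignment, and grid-based contact detection.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <unordered_set>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Least-squares rigid transform mapping a onto b: y = R x + t.
// a, b are k x 3 with matched rows.
static void kabsch_core(const arma::mat& a, const arma::mat& b,
                        arma::mat& R, arma::vec& t, double& rmsd) {
  arma::rowvec ca = arma::mean(a, 0), cb = arma::mean(b, 0);
  arma::mat A = a.each_row() - ca, B = b.each_row() - cb;
  arma::mat H = A.t() * B;            // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;     // reflection correction
  R = V * D * U.t();
  t = cb.t() - R * ca.t();
  arma::mat res = (a * R.t());
  res.each_row() += t.t();
  res -= b;
  rmsd = std::sqrt(arma::accu(arma::square(res)) / a.n_rows);
}

static arma::mat apply_rt(const arma::mat& x, const arma::mat& R, const arma::vec& t) {
  arma::mat y = x * R.t();
  y.each_row() += t.t();
  return y;
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& a, const arma::mat& b) {
  arma::mat R;
  arma::vec t;
  double rmsd;
  kabsch_core(a, b, R, t, rmsd);
  return List::create(_["R"] = R, _["t"] = t, _["rmsd"] = rmsd);
}

// TM-score style search for the best superposition of a fixed residue
// correspondence: seed on sliding fragments, then iteratively re-superpose
// on the subset of pairs closer than a growing cutoff.
// a, b: k x 3 matched coordinates; score = sum 1/(1+(d/d0)^2) / Lnorm.
static double tmscore_core(const arma::mat& a, const arma::mat& b,
                           double Lnorm, double d0,
                           arma::mat& Rbest, arma::vec& tbest) {
  const int k = a.n_rows;
  double best = -1.0;
  const double d0sq = d0 * d0;
  const double dcut0 = std::max(4.5, d0);
  int Lmin = std::min(k, 4);
  std::vector<int> Linits;
  for (int L = k; L > Lmin; L = L / 2) Linits.push_back(L);
  Linits.push_back(Lmin);
  arma::mat R;
  arma::vec t;
  double rms;
  for (int L : Linits) {
    int step = std::max(1, L / 2);
    for (int start = 0; start + L <= k; start += step) {
      arma::uvec sel(L);
      for (int i = 0; i < L; ++i) sel[i] = start + i;
      for (int iter = 0; iter < 20; ++iter) {
        if (sel.n_elem < 3) break;
        kabsch_core(a.rows(sel), b.rows(sel), R, t, rms);
        arma::mat ya = apply_rt(a, R, t);
        arma::vec d2 = arma::sum(arma::square(ya - b), 1);
        double sc = 0.0;
        for (int i = 0; i < k; ++i) sc += 1.0 / (1.0 + d2[i] / d0sq);
        sc /= Lnorm;
        if (sc > best) { best = sc; Rbest = R; tbest = t; }
        double dcut = dcut0;
        arma::uvec sel2;
        for (;;) {
          sel2 = arma::find(d2 < dcut * dcut);
          if ((int)sel2.n_elem >= 3 || dcut > 8.0) break;
          dcut += 0.5;
        }
        if ((int)sel2.n_elem < 3) break;
        if (sel2.n_elem == sel.n_elem && arma::all(sel2 == sel)) break;
        sel = sel2;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_tmscore(const arma::mat& a, const arma::mat& b, double Lnorm, double d0) {
  arma::mat R;
  arma::vec t;
  double sc = tmscore_core(a, b, Lnorm, d0, R, t);
  arma::mat Rf;
  arma::vec tf;
  double rmsd_all;
  kabsch_core(a, b, Rf, tf, rmsd_all);   // plain full-set superposition RMSD
  return List::create(_["score"] = sc, _["R"] = R, _["t"] = t,
                      _["rmsd_aligned"] = rmsd_all);
}

// Needleman-Wunsch with linear gap penalty and free end gaps, maximizing
// sum of S over matched cells. Returns monotone 1-based pairs.
static std::vector<std::pair<int,int> > nwdp_core(const arma::mat& S, double gap) {
  const int n = S.n_rows, m = S.n_cols;
  arma::mat H(n + 1, m + 1, arma::fill::zeros);
  arma::Mat<int> tb(n + 1, m + 1, arma::fill::zeros); // 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double up = H(i - 1, j) + ((j == m) ? 0.0 : gap);
      double left = H(i, j - 1) + ((i == n) ? 0.0 : gap);
      if (diag >= up && diag >= left) { H(i, j) = diag; tb(i, j) = 1; }
      else if (up >= left)            { H(i, j) = up;   tb(i, j) = 2; }
      else                            { H(i, j) = left; tb(i, j) = 3; }
    }
  }
  std::vector<std::pair<int,int> > pairs;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    int mv = tb(i, j);
    if (mv == 1) { pairs.push_back(std::make_pair(i, j)); --i; --j; }
    else if (mv == 2) --i;
    else if (mv == 3) --j;
    else break;
  }
  std::reverse(pairs.begin(), pairs.end());
  return pairs;
}

// [[Rcpp::export]]
IntegerMatrix cpp_nwdp(const arma::mat& S, double gap) {
  std::vector<std::pair<int,int> > pr = nwdp_core(S, gap);
  IntegerMatrix out(pr.size(), 2);
  for (size_t r = 0; r < pr.size(); ++r) { out(r, 0) = pr[r].first; out(r, 1) = pr[r].second; }
  return out;
}

static std::string ali_key(const std::vector<std::pair<int,int> >& a) {
  std::string k;
  k.reserve(a.size() * 8);
  for (size_t i = 0; i < a.size(); ++i) {
    k += std::to_string(a[i].first);
    k += ',';
    k += std::to_string(a[i].second);
    k += ';';
  }
  return k;
}

// Iterative TM-align-style structural alignment.
// a: N x 3 target, b: M x 3 template. Seeds: gapless threading offsets plus
// any caller-supplied alignments (e.g. a descriptor-based DP seed for RNA).
// Returns the alignment with the highest TM-style score normalized by Lnorm.
// [[Rcpp::export]]
List cpp_struct_align(const arma::mat& a, const arma::mat& b,
                      double Lnorm, double d0, List extra_seeds,
                      double gap = -0.6, int max_iter = 10) {
  const int n = a.n_rows, m = b.n_cols == 3 ? (int)b.n_rows : 0;
  const double d0sq = d0 * d0;
  std::vector<std::vector<std::pair<int,int> > > seeds;
  int f = std::min(4, std::min(n, m));
  int lo = -(m - f), hi = n - f;
  int span = hi - lo + 1;
  int step = std::max(1, span / 40);
  for (int o = lo; o <= hi; o += step) {
    std::vector<std::pair<int,int> > s;
    for (int i = 1; i <= n; ++i) {
      int j = i - o;
      if (j >= 1 && j <= m) s.push_back(std::make_pair(i, j));
    }
    if ((int)s.size() >= 3) seeds.push_back(s);
  }
  { // make sure the zero offset (index alignment) is present
    std::vector<std::pair<int,int> > s;
    for (int i = 1; i <= std::min(n, m); ++i) s.push_back(std::make_pair(i, i));
    seeds.push_back(s);
  }
  for (int e = 0; e < extra_seeds.size(); ++e) {
    IntegerMatrix sm = extra_seeds[e];
    std::vector<std::pair<int,int> > s;
    for (int r = 0; r < sm.nrow(); ++r) s.push_back(std::make_pair(sm(r, 0), sm(r, 1)));
    if ((int)s.size() >= 3) seeds.push_back(s);
  }

  double best_score = -1.0;
  std::vector<std::pair<int,int> > best_ali;
  arma::mat bestR;
  arma::vec bestt;
  std::unordered_set<std::string> scored;   // final alignments already evaluated
  arma::mat R;
  arma::vec t;
  double rms;
  const double dcut0 = std::max(4.5, d0);

  for (size_t si = 0; si < seeds.size(); ++si) {
    std::vector<std::pair<int,int> > ali = seeds[si];
    std::unordered_set<std::string> seen;
    for (int iter = 0; iter < max_iter; ++iter) {
      // superpose on current pairs, then refine on close pairs
      arma::mat pa(ali.size(), 3), pb(ali.size(), 3);
      for (size_t r = 0; r < ali.size(); ++r) {
        pa.row(r) = a.row(ali[r].first - 1);
        pb.row(r) = b.row(ali[r].second - 1);
      }
      kabsch_core(pa, pb, R, t, rms);
      for (int refine = 0; refine < 3; ++refine) {
        arma::mat ya = apply_rt(pa, R, t);
        arma::vec d2 = arma::sum(arma::square(ya - pb), 1);
        double dcut = dcut0;
        arma::uvec sel;
        for (;;) {
          sel = arma::find(d2 < dcut * dcut);
          if ((int)sel.n_elem >= 3 || dcut > 8.0) break;
          dcut += 0.5;
        }
        if ((int)sel.n_elem < 3) break;
        kabsch_core(pa.rows(sel), pb.rows(sel), R, t, rms);
      }
      // score matrix in the refined frame, then DP for a new alignment
      arma::mat ya = apply_rt(a, R, t);
      arma::mat S(n, m);
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) {
          double d2 = arma::accu(arma::square(ya.row(i) - b.row(j)));
          S(i, j) = 1.0 / (1.0 + d2 / d0sq);
        }
      std::vector<std::pair<int,int> > ali2 = nwdp_core(S, gap);
      if ((int)ali2.size() < 3) break;
      std::string key = ali_key(ali2);
      bool repeat = (key == ali_key(ali)) || seen.count(key) > 0;
      ali = ali2;
      seen.insert(key);
      if (repeat) break;
    }
    // full rotation search on the converged correspondence
    std::string key = ali_key(ali);
    if (scored.count(key)) continue;
    scored.insert(key);
    arma::mat pa(ali.size(), 3), pb(ali.size(), 3);
    for (size_t r = 0; r < ali.size(); ++r) {
      pa.row(r) = a.row(ali[r].first - 1);
      pb.row(r) = b.row(ali[r].second - 1);
    }
    arma::mat Rf;
    arma::vec tf;
    double sc = tmscore_core(pa, pb, Lnorm, d0, Rf, tf);
    if (sc > best_score) { best_score = sc; best_ali = ali; bestR = Rf; bestt = tf; }
  }

  IntegerMatrix pairs(best_ali.size(), 2);
  arma::mat pa(best_ali.size(), 3), pb(best_ali.size(), 3);
  for (size_t r = 0; r < best_ali.size(); ++r) {
    pairs(r, 0) = best_ali[r].first;
    pairs(r, 1) = best_ali[r].second;
    pa.row(r) = a.row(best_ali[r].first - 1);
    pb.row(r) = b.row(best_ali[r].second - 1);
  }
  arma::mat Rf;
  arma::vec tf;
  double rmsd_all;
  kabsch_core(pa, pb, Rf, tf, rmsd_all);
  return List::create(_["pairs"] = pairs, _["score"] = best_score,
                      _["R"] = bestR, _["t"] = bestt,
                      _["rmsd_aligned"] = rmsd_all);
}

// ---- spatial grid for contact detection --------------------------------

static inline long long cell_key(int ix, int iy, int iz) {
  return ((long long)(ix + 1048576) << 42) | ((long long)(iy + 1048576) << 21) |
         (long long)(iz + 1048576);
}

// Residue-level contacts: residue i of a is in contact if any of its atoms
// lies strictly within `cutoff` of any atom of b (and vice versa).
// axyz: Na x 3, ares: residue ordinal (1-based) per atom of a; same for b.
// [[Rcpp::export]]
List cpp_interface(const arma::mat& axyz, const IntegerVector& ares,
                   const arma::mat& bxyz, const IntegerVector& bres,
                   double cutoff) {
  const double c2 = cutoff * cutoff;
  std::unordered_map<long long, std::vector<int> > grid;
  const int nb = bxyz.n_rows;
  for (int j = 0; j < nb; ++j) {
    int ix = (int)std::floor(bxyz(j, 0) / cutoff);
    int iy = (int)std::floor(bxyz(j, 1) / cutoff);
    int iz = (int)std::floor(bxyz(j, 2) / cutoff);
    grid[cell_key(ix, iy, iz)].push_back(j);
  }
  std::set<int> aset, bset;
  const int na = axyz.n_rows;
  for (int i = 0; i < na; ++i) {
    int ix = (int)std::floor(axyz(i, 0) / cutoff);
    int iy = (int)std::floor(axyz(i, 1) / cutoff);
    int iz = (int)std::floor(axyz(i, 2) / cutoff);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (size_t q = 0; q < it->second.size(); ++q) {
            int j = it->second[q];
            double d2 = arma::accu(arma::square(axyz.row(i) - bxyz.row(j)));
            if (d2 < c2) { aset.insert(ares[i]); bset.insert(bres[j]); }
          }
        }
  }
  return List::create(_["a"] = IntegerVector(aset.begin(), aset.end()),
                      _["b"] = IntegerVector(bset.begin(), bset.end()));
}

// Number of inter-molecular atom pairs strictly within cutoff.
// [[Rcpp::export]]
int cpp_count_close(const arma::mat& axyz, const arma::mat& bxyz, double cutoff) {
  const double c2 = cutoff * cutoff;
  std::unordered_map<long long, std::vector<int> > grid;
  for (int j = 0; j < (int)bxyz.n_rows; ++j) {
    int ix = (int)std::floor(bxyz(j, 0) / cutoff);
    int iy = (int)std::floor(bxyz(j, 1) / cutoff);
    int iz = (int)std::floor(bxyz(j, 2) / cutoff);
    grid[cell_key(ix, iy, iz)].push_back(j);
  }
  int count = 0;
  for (int i = 0; i < (int)axyz.n_rows; ++i) {
    int ix = (int)std::floor(axyz(i, 0) / cutoff);
    int iy = (int)std::floor(axyz(i, 1) / cutoff);
    int iz = (int)std::floor(axyz(i, 2) / cutoff);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (size_t q = 0; q < it->second.size(); ++q) {
            double d2 = arma::accu(arma::square(axyz.row(i) - bxyz.row(it->second[q])));
            if (d2 < c2) ++count;
          }
        }
  }
  return count;
}
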