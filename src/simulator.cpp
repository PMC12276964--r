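// Continuous-space individual-based forward simulator.
//
// Life cycle per tick: reproduction (every pre-cycle individual draws a mate
// within 3*sigma_m by truncated-Gaussian weight and produces a Poisson(1/L)
// number of offspring), dispersal (offspring placed at mother + Gaussian
// displacement with locally interpolated sigma_f; proposals outside the
// habitat or mask are discarded), then competition-based mortality applied to
// everyone including newborns. All randomness comes from R's RNG so that
// set.seed() gives bit-identical trajectories.
//
// Kernel sums are exact truncated-Gaussian sums over all neighbours within
// the cutoff; the exponential is evaluated through a dense interpolation
// table (absolute error < 1e-9, see KernelTable) and each unordered pair is
// visited once via a half-stencil sweep of the bucket grid.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct KernelTable {
  // piecewise-linear table of exp(-d2 * inv2s2) for d2 in [0, max_d2];
  // with 1 << 16 bins the interpolation error is below 1e-9
  double scale;
  std::vector<double> tab;
  void init(double max_d2, double inv2s2) {
    const int B = 1 << 16;
    scale = B / max_d2;
    tab.resize(B + 2);
    for (int k = 0; k <= B + 1; ++k) {
      tab[k] = std::exp(-(k / scale) * inv2s2);
    }
  }
  inline double eval(double d2) const {
    double u = d2 * scale;
    int k = (int)u;
    double f = u - k;
    return tab[k] * (1.0 - f) + tab[k + 1] * f;
  }
};

struct Grid {
  // uniform-bucket spatial index over [0, w]^2
  double cell;
  int nb;
  std::vector<int> head;   // bucket -> first index into order
  std::vector<int> order;  // indices grouped by bucket

  void build(const std::vector<double>& x, const std::vector<double>& y,
             int n, double w, double cell_size) {
    cell = cell_size;
    nb = std::max(1, (int)std::ceil(w / cell));
    head.assign(nb * nb + 1, 0);
    order.resize(n);
    std::vector<int> bucket(n);
    for (int i = 0; i < n; ++i) {
      int bx = std::min(nb - 1, (int)(x[i] / cell));
      int by = std::min(nb - 1, (int)(y[i] / cell));
      bucket[i] = bx + by * nb;
      head[bucket[i] + 1]++;
    }
    for (int b = 0; b < nb * nb; ++b) head[b + 1] += head[b];
    std::vector<int> cursor(head.begin(), head.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[bucket[i]]++] = i;
  }

  // visit every unordered pair within distance^2 <= max_d2 exactly once
  template <class F>
  void for_pairs(const std::vector<double>& x, const std::vector<double>& y,
                 double max_d2, F&& fn) const {
    // half stencil: same bucket (i<j) plus 4 of the 8 neighbours
    static const int DX[4] = {1, 1, 0, -1};
    static const int DY[4] = {0, 1, 1, 1};
    for (int by = 0; by < nb; ++by) {
      for (int bx = 0; bx < nb; ++bx) {
        int b = bx + by * nb;
        for (int t = head[b]; t < head[b + 1]; ++t) {
          int i = order[t];
          for (int u = t + 1; u < head[b + 1]; ++u) {
            int j = order[u];
            double dx = x[j] - x[i], dy = y[j] - y[i];
            double d2 = dx * dx + dy * dy;
            if (d2 <= max_d2) fn(i, j, d2);
          }
        }
        for (int s = 0; s < 4; ++s) {
          int bxx = bx + DX[s], byy = by + DY[s];
          if (bxx < 0 || bxx >= nb || byy < 0 || byy >= nb) continue;
          int b2 = bxx + byy * nb;
          for (int t = head[b]; t < head[b + 1]; ++t) {
            int i = order[t];
            for (int u = head[b2]; u < head[b2 + 1]; ++u) {
              int j = order[u];
              double dx = x[j] - x[i], dy = y[j] - y[i];
              double d2 = dx * dx + dy * dy;
              if (d2 <= max_d2) fn(i, j, d2);
            }
          }
        }
      }
    }
  }
};

inline double interp_map(const NumericMatrix& m, double x, double y, int w) {
  // bilinear interpolation of cell-center values, clamped at the edges;
  // cell (i, j) has center (i - 0.5, j - 0.5) in [0, w]^2 (1-based i, j)
  if (w == 1) return m(0, 0);
  double u = std::min(std::max(x - 0.5, 0.0), (double)(w - 1));
  double v = std::min(std::max(y - 0.5, 0.0), (double)(w - 1));
  int i0 = std::min((int)u, w - 2);
  int j0 = std::min((int)v, w - 2);
  double fx = u - i0, fy = v - j0;
  return m(i0, j0) * (1 - fx) * (1 - fy) + m(i0 + 1, j0) * fx * (1 - fy) +
         m(i0, j0 + 1) * (1 - fx) * fy + m(i0 + 1, j0 + 1) * fx * fy;
}

inline int cell_index(double coord, int w) {
  int c = (int)coord;
  if (c >= w) c = w - 1;
  if (c < 0) c = 0;
  return c;
}

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix sigma_map, NumericMatrix k_map,
              LogicalMatrix mask, bool has_mask,
              double sigma_m, double sigma_c, double L, double comp_cost,
              int n_cycles, int burn_in,
              double genome_length, double recomb_rate,
              bool record_ancestry, bool record_realized,
              int n_init) {
  const int w = sigma_map.nrow();
  const double W = (double)w;
  RNGScope scope;

  auto habitable_cell = [&](double x, double y) -> bool {
    if (!has_mask) return true;
    return mask(cell_index(x, w), cell_index(y, w));
  };

  // --- initial population ---
  if (n_init < 0) {
    double ksum = 0;
    for (int i = 0; i < w * w; ++i) ksum += k_map[i];
    n_init = (int)std::lround(ksum / (w * w) * W * W);
  }
  if (n_init <= 0) stop("initial population size is zero");

  std::vector<double> x, y;       // current population
  std::vector<int> gid;           // global individual ids (0-based)
  std::vector<int> birth_cycle;   // per global id
  long long next_gid = 0;

  x.reserve(2 * n_init); y.reserve(2 * n_init); gid.reserve(2 * n_init);
  for (int i = 0; i < n_init; ++i) {
    double px, py;
    do {
      px = R::runif(0.0, W);
      py = R::runif(0.0, W);
    } while (!habitable_cell(px, py));
    x.push_back(px); y.push_back(py);
    gid.push_back((int)next_gid++);
    birth_cycle.push_back(0);
  }

  // ancestry tables (tskit-style edges over [0, genome_length))
  std::vector<double> e_left, e_right;
  std::vector<int> e_parent, e_child;
  std::vector<int> mom_of, dad_of;
  if (record_ancestry) {
    mom_of.assign(n_init, -1);
    dad_of.assign(n_init, -1);
  }

  // realized-map accumulators
  std::vector<double> dens_sum(w * w, 0.0);
  std::vector<double> disp_sumsq(w * w, 0.0);
  std::vector<double> disp_n(w * w, 0.0);
  int census_cycles = 0;

  const double max_m2 = 9.0 * sigma_m * sigma_m;
  const double max_c2 = 9.0 * sigma_c * sigma_c;
  const double kern0 = 1.0 / (2.0 * M_PI * sigma_c * sigma_c);
  const double fecun = 1.0 / L;
  const double bucket_edge = std::max(std::max(3.0 * sigma_m, 3.0 * sigma_c),
                                      1e-8);

  KernelTable mate_kern, comp_kern;
  mate_kern.init(max_m2, 1.0 / (2.0 * sigma_m * sigma_m));
  comp_kern.init(max_c2, 1.0 / (2.0 * sigma_c * sigma_c));

  Grid grid;
  // CSR adjacency scratch for mate choice
  std::vector<int> adj_i, adj_j, adj_off, adj_nbr, cursor;
  std::vector<double> adj_w, adj_wgt, wsum;
  std::vector<int> pop_size; // post-mortality census per cycle
  pop_size.reserve(n_cycles);

  int extinct_at = -1;

  auto transmit = [&](int parent_gid, int child_node) {
    // one genome copy from parent to child with recombination
    int nb = (int)R::rpois(recomb_rate * genome_length);
    int hap = (R::unif_rand() < 0.5) ? 0 : 1;
    int pa = 2 * parent_gid + hap, pb = 2 * parent_gid + (1 - hap);
    if (nb == 0) {
      e_left.push_back(0.0); e_right.push_back(genome_length);
      e_parent.push_back(pa); e_child.push_back(child_node);
      return;
    }
    std::vector<double> bp(nb);
    for (int b = 0; b < nb; ++b) bp[b] = R::runif(0.0, genome_length);
    std::sort(bp.begin(), bp.end());
    bp.erase(std::unique(bp.begin(), bp.end()), bp.end());
    double left = 0.0;
    int cur = pa;
    for (size_t b = 0; b < bp.size(); ++b) {
      e_left.push_back(left); e_right.push_back(bp[b]);
      e_parent.push_back(cur); e_child.push_back(child_node);
      left = bp[b];
      cur = (cur == pa) ? pb : pa;
    }
    e_left.push_back(left); e_right.push_back(genome_length);
    e_parent.push_back(cur); e_child.push_back(child_node);
  };

  for (int cycle = 1; cycle <= n_cycles; ++cycle) {
    const int n = (int)x.size();
    if (n == 0) { extinct_at = cycle; break; }
    const bool recording = record_realized && cycle > burn_in;

    // --- reproduction + dispersal ---
    grid.build(x, y, n, W, bucket_edge);
    adj_i.clear(); adj_j.clear(); adj_w.clear();
    wsum.assign(n, 0.0);
    grid.for_pairs(x, y, max_m2, [&](int i, int j, double d2) {
      double g = mate_kern.eval(d2);
      adj_i.push_back(i); adj_j.push_back(j); adj_w.push_back(g);
      wsum[i] += g; wsum[j] += g;
    });
    // counting-sort the symmetric adjacency by focal index
    const size_t np = adj_i.size();
    adj_off.assign(n + 1, 0);
    for (size_t t = 0; t < np; ++t) {
      adj_off[adj_i[t] + 1]++; adj_off[adj_j[t] + 1]++;
    }
    for (int i = 0; i < n; ++i) adj_off[i + 1] += adj_off[i];
    adj_nbr.resize(2 * np); adj_wgt.resize(2 * np);
    cursor.assign(adj_off.begin(), adj_off.end() - 1);
    for (size_t t = 0; t < np; ++t) {
      int i = adj_i[t], j = adj_j[t];
      adj_nbr[cursor[i]] = j; adj_wgt[cursor[i]++] = adj_w[t];
      adj_nbr[cursor[j]] = i; adj_wgt[cursor[j]++] = adj_w[t];
    }

    std::vector<double> nx_, ny_;
    std::vector<int> ngid;
    for (int i = 0; i < n; ++i) {
      if (adj_off[i + 1] == adj_off[i]) continue; // no neighbour in range
      double u = R::unif_rand() * wsum[i];
      int mate = adj_nbr[adj_off[i + 1] - 1];
      for (int t = adj_off[i]; t < adj_off[i + 1]; ++t) {
        u -= adj_wgt[t];
        if (u <= 0) { mate = adj_nbr[t]; break; }
      }
      int n_off = (int)R::rpois(fecun);
      if (n_off == 0) continue;
      double sig_loc = interp_map(sigma_map, x[i], y[i], w);
      double sf2 = sig_loc * sig_loc - 0.5 * sigma_m * sigma_m;
      double sf = sf2 > 0 ? std::sqrt(sf2) : 0.0;
      for (int o = 0; o < n_off; ++o) {
        double ox = x[i] + R::norm_rand() * sf;
        double oy = y[i] + R::norm_rand() * sf;
        if (ox < 0 || ox > W || oy < 0 || oy > W) continue; // not produced
        if (!habitable_cell(ox, oy)) continue;
        nx_.push_back(ox); ny_.push_back(oy);
        int child = (int)next_gid++;
        ngid.push_back(child);
        birth_cycle.push_back(cycle);
        if (record_ancestry) {
          mom_of.push_back(gid[i]);
          dad_of.push_back(gid[mate]);
          transmit(gid[i], 2 * child);
          transmit(gid[mate], 2 * child + 1);
        }
        if (recording) {
          int ci = cell_index(ox, w), cj = cell_index(oy, w);
          double dmx = ox - x[i], dmy = oy - y[i];
          double dfx = ox - x[mate], dfy = oy - y[mate];
          disp_sumsq[ci + cj * w] +=
            dmx * dmx + dmy * dmy + dfx * dfx + dfy * dfy;
          disp_n[ci + cj * w] += 4.0;
        }
      }
    }

    // --- mortality over parents + newborns ---
    std::vector<double> ax(x), ay(y);
    std::vector<int> agid(gid);
    ax.insert(ax.end(), nx_.begin(), nx_.end());
    ay.insert(ay.end(), ny_.begin(), ny_.end());
    agid.insert(agid.end(), ngid.begin(), ngid.end());
    const int na = (int)ax.size();
    grid.build(ax, ay, na, W, bucket_edge);
    std::vector<double> eta(na, 0.0);
    grid.for_pairs(ax, ay, max_c2, [&](int i, int j, double d2) {
      double g = kern0 * comp_kern.eval(d2);
      eta[i] += g; eta[j] += g;
    });
    std::vector<double> sx, sy;
    std::vector<int> sgid;
    sx.reserve(na); sy.reserve(na); sgid.reserve(na);
    for (int i = 0; i < na; ++i) {
      double k_loc = interp_map(k_map, ax[i], ay[i], w);
      if (k_loc < 1e-10) k_loc = 1e-10;
      double p = 1.0 / (1.0 + comp_cost * eta[i] / k_loc);
      if (R::unif_rand() < p) {
        sx.push_back(ax[i]); sy.push_back(ay[i]); sgid.push_back(agid[i]);
      }
    }
    x.swap(sx); y.swap(sy); gid.swap(sgid);
    pop_size.push_back((int)x.size());

    if (recording) {
      census_cycles++;
      for (size_t i = 0; i < x.size(); ++i) {
        dens_sum[cell_index(x[i], w) + cell_index(y[i], w) * w] += 1.0;
      }
    }
    if (x.empty()) { extinct_at = cycle; break; }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix density(w, w), dispersal(w, w);
  NumericMatrix counts(w, w);
  if (record_realized && census_cycles > 0) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < w; ++i) {
        density(i, j) = dens_sum[i + j * w] / census_cycles; // cell area = 1
        counts(i, j) = disp_n[i + j * w];
        dispersal(i, j) = disp_n[i + j * w] > 0
          ? std::sqrt(disp_sumsq[i + j * w] / disp_n[i + j * w])
          : NA_REAL;
      }
    }
  }

  List anc = R_NilValue;
  if (record_ancestry) {
    anc = List::create(
      _["birth_cycle"] = IntegerVector(birth_cycle.begin(), birth_cycle.end()),
      _["mother"] = IntegerVector(mom_of.begin(), mom_of.end()),
      _["father"] = IntegerVector(dad_of.begin(), dad_of.end()),
      _["edge_left"] = NumericVector(e_left.begin(), e_left.end()),
      _["edge_right"] = NumericVector(e_right.begin(), e_right.end()),
      _["edge_parent"] = IntegerVector(e_parent.begin(), e_parent.end()),
      _["edge_child"] = IntegerVector(e_child.begin(), e_child.end()));
  }

  return List::create(
    _["x"] = NumericVector(x.begin(), x.end()),
    _["y"] = NumericVector(y.begin(), y.end()),
    _["gid"] = IntegerVector(gid.begin(), gid.end()),
    _["n_total_born"] = (double)next_gid,
    _["extinct_at"] = extinct_at,
    _["density"] = density,
    _["dispersal"] = dispersal,
    _["event_counts"] = counts,
    _["census_cycles"] = census_cycles,
    _["pop_size"] = IntegerVector(pop_size.begin(), pop_size.end()),
    _["ancestry"] = anc);
}

// [[Rcpp::export(name = ".eta_core")]]
NumericVector eta_core(NumericVector x, NumericVector y, double sigma_c) {
  // brute-force exact interaction strength, for testing and calibration
  const int n = x.size();
  const double max_c2 = 9.0 * sigma_c * sigma_c;
  const double inv2sc2 = 1.0 / (2.0 * sigma_c * sigma_c);
  const double kern0 = 1.0 / (2.0 * M_PI * sigma_c * sigma_c);
  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      double d2 = dx * dx + dy * dy;
      if (d2 <= max_c2) s += kern0 * std::exp(-d2 * inv2sc2);
    }
    eta[i] = s;
  }
  return eta;
}
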