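// Metropolis Monte-Carlo sampler for coarse-grained tail bead chains
// tethered to a rigid microtubule lattice. One bead per residue; harmonic
// bonds; hard cylindrical wall at the lattice surface; square-well
// attraction between acidic beads and the basic site beads of the tail's
// own cis/trans partner subunits. kT = temperature; distances in Angstrom.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double min_image_dz(double dz, double box, bool periodic) {
  if (periodic) dz -= box * std::round(dz / box);
  return dz;
}

struct McState {
  int n_tails, n_beads;
  std::vector<double> x, y, z;           // bead coords, tail-major
  const NumericMatrix &anchors;
  const NumericMatrix &site_xyz;
  const IntegerVector &site_site;        // site id (1..4) per site bead
  const IntegerVector &site_offset;      // n_tails+1, bead ranges per tail
  const NumericVector &eps;              // well depth per site id
  const std::vector<bool> &acidic;       // per within-tail bead index
  double b0, k, wall2, range2, box;
  bool periodic;

  McState(NumericMatrix coords, const NumericMatrix &anchors_,
          const NumericMatrix &site_xyz_, const IntegerVector &site_site_,
          const IntegerVector &site_offset_, const NumericVector &eps_,
          const std::vector<bool> &acidic_, int n_tails_, int n_beads_,
          double b0_, double k_, double wall_, double range_, double box_,
          bool periodic_)
      : n_tails(n_tails_), n_beads(n_beads_), anchors(anchors_),
        site_xyz(site_xyz_), site_site(site_site_), site_offset(site_offset_),
        eps(eps_), acidic(acidic_), b0(b0_), k(k_), wall2(wall_ * wall_),
        range2(range_ * range_), box(box_), periodic(periodic_) {
    int n = coords.nrow();
    x.resize(n); y.resize(n); z.resize(n);
    for (int i = 0; i < n; ++i) {
      x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
    }
  }

  inline int gi(int t, int b) const { return t * n_beads + b; }

  inline bool inside_wall(double px, double py) const {
    return px * px + py * py < wall2;
  }

  // harmonic bond energy between bead b of tail t and its predecessor
  inline double bond_e(double d) const {
    double dd = d - b0;
    return 0.5 * k * dd * dd;
  }

  inline double dist(double ax, double ay, double az, double bx, double by,
                     double bz) const {
    double dx = ax - bx, dy = ay - by;
    double dz = min_image_dz(az - bz, box, periodic);
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  // bond energy of the two bonds touching bead b, with bead b at (px,py,pz)
  double local_bond(int t, int b, double px, double py, double pz) const {
    double e = 0.0;
    double ax, ay, az;
    if (b == 0) { ax = anchors(t, 0); ay = anchors(t, 1); az = anchors(t, 2); }
    else { int g = gi(t, b - 1); ax = x[g]; ay = y[g]; az = z[g]; }
    e += bond_e(dist(px, py, pz, ax, ay, az));
    if (b + 1 < n_beads) {
      int g = gi(t, b + 1);
      e += bond_e(dist(px, py, pz, x[g], y[g], z[g]));
    }
    return e;
  }

  // square-well attraction of one acidic bead at (px,py,pz) to tail t's sites
  double site_e(int t, double px, double py, double pz) const {
    double e = 0.0;
    for (int s = site_offset[t]; s < site_offset[t + 1]; ++s) {
      double dx = px - site_xyz(s, 0), dy = py - site_xyz(s, 1);
      double dz = min_image_dz(pz - site_xyz(s, 2), box, periodic);
      if (dx * dx + dy * dy + dz * dz <= range2)
        e -= eps[site_site[s] - 1];
    }
    return e;
  }

  double total_energy(double *bond_out, double *site_out) const {
    double eb = 0.0, es = 0.0;
    for (int t = 0; t < n_tails; ++t) {
      for (int b = 0; b < n_beads; ++b) {
        int g = gi(t, b);
        double ax, ay, az;
        if (b == 0) { ax = anchors(t, 0); ay = anchors(t, 1); az = anchors(t, 2); }
        else { int h = gi(t, b - 1); ax = x[h]; ay = y[h]; az = z[h]; }
        eb += bond_e(dist(x[g], y[g], z[g], ax, ay, az));
        if (acidic[b]) es += site_e(t, x[g], y[g], z[g]);
      }
    }
    if (bond_out) *bond_out = eb;
    if (site_out) *site_out = es;
    return eb + es;
  }
};

// [[Rcpp::export]]
List cg_mc_run(NumericMatrix coords, NumericMatrix anchors,
               NumericMatrix site_xyz, IntegerVector site_site,
               IntegerVector site_offset, NumericVector eps,
               LogicalVector acidic_bead, int n_tails, int n_beads,
               double bond_length, double bond_k, double wall_radius,
               double well_range, double temperature, double max_disp,
               int n_sweeps, int frame_stride, int pivot_every,
               double axial_box, bool periodic) {
  if (coords.nrow() != n_tails * n_beads)
    stop("coordinate count does not match n_tails * n_beads");
  std::vector<bool> acidic(n_beads);
  for (int b = 0; b < n_beads; ++b) acidic[b] = acidic_bead[b];
  McState st(coords, anchors, site_xyz, site_site, site_offset, eps, acidic,
             n_tails, n_beads, bond_length, bond_k, wall_radius, well_range,
             axial_box, periodic);
  const double invT = 1.0 / temperature;

  int n_frames = frame_stride > 0 ? n_sweeps / frame_stride : 0;
  NumericVector frames(Dimension((R_xlen_t)(n_tails * n_beads), 3,
                                 std::max(n_frames, 1)));
  long acc_disp = 0, try_disp = 0, acc_piv = 0, try_piv = 0;
  int frame_i = 0;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    // one single-bead trial move per bead
    for (int t = 0; t < n_tails; ++t) {
      for (int b = 0; b < n_beads; ++b) {
        int g = st.gi(t, b);
        double nx = st.x[g] + (unif_rand() * 2.0 - 1.0) * max_disp;
        double ny = st.y[g] + (unif_rand() * 2.0 - 1.0) * max_disp;
        double nz = st.z[g] + (unif_rand() * 2.0 - 1.0) * max_disp;
        ++try_disp;
        if (st.inside_wall(nx, ny)) continue;  // hard wall: reject
        double de = st.local_bond(t, b, nx, ny, nz) -
                    st.local_bond(t, b, st.x[g], st.y[g], st.z[g]);
        if (acidic[b])
          de += st.site_e(t, nx, ny, nz) - st.site_e(t, st.x[g], st.y[g], st.z[g]);
        if (de <= 0.0 || unif_rand() < std::exp(-de * invT)) {
          st.x[g] = nx; st.y[g] = ny; st.z[g] = nz;
          ++acc_disp;
        }
      }
    }
    // pivot move: rotate the chain downstream of a random bead
    if (pivot_every > 0 && sweep % pivot_every == 0) {
      for (int t = 0; t < n_tails; ++t) {
        int p = (int)(unif_rand() * n_beads);
        if (p >= n_beads) p = n_beads - 1;
        if (p == n_beads - 1) continue;  // nothing downstream
        ++try_piv;
        // uniform random axis, uniform angle in (-pi, pi)
        double u = 2.0 * unif_rand() - 1.0, phi = 2.0 * M_PI * unif_rand();
        double sq = std::sqrt(std::max(0.0, 1.0 - u * u));
        double axx = sq * std::cos(phi), axy = sq * std::sin(phi), axz = u;
        double ang = (2.0 * unif_rand() - 1.0) * M_PI;
        double c = std::cos(ang), s = std::sin(ang);
        int g0 = st.gi(t, p);
        double cx = st.x[g0], cy = st.y[g0], cz = st.z[g0];
        int nrot = n_beads - 1 - p;
        std::vector<double> nx(nrot), ny(nrot), nz(nrot);
        bool wall_hit = false;
        double de = 0.0;
        for (int j = 0; j < nrot; ++j) {
          int g = st.gi(t, p + 1 + j);
          double vx = st.x[g] - cx, vy = st.y[g] - cy, vz = st.z[g] - cz;
          // Rodrigues rotation
          double dot = axx * vx + axy * vy + axz * vz;
          double rx = vx * c + (axy * vz - axz * vy) * s + axx * dot * (1 - c);
          double ry = vy * c + (axz * vx - axx * vz) * s + axy * dot * (1 - c);
          double rz = vz * c + (axx * vy - axy * vx) * s + axz * dot * (1 - c);
          nx[j] = cx + rx; ny[j] = cy + ry; nz[j] = cz + rz;
          if (st.inside_wall(nx[j], ny[j])) { wall_hit = true; break; }
          if (acidic[p + 1 + j]) {
            de += st.site_e(t, nx[j], ny[j], nz[j]) -
                  st.site_e(t, st.x[g], st.y[g], st.z[g]);
          }
        }
        if (wall_hit) continue;
        if (de <= 0.0 || unif_rand() < std::exp(-de * invT)) {
          for (int j = 0; j < nrot; ++j) {
            int g = st.gi(t, p + 1 + j);
            st.x[g] = nx[j]; st.y[g] = ny[j]; st.z[g] = nz[j];
          }
          ++acc_piv;
        }
      }
    }
    if (frame_stride > 0 && sweep % frame_stride == 0 && frame_i < n_frames) {
      R_xlen_t n = (R_xlen_t)(n_tails * n_beads);
      for (R_xlen_t i = 0; i < n; ++i) {
        frames[i + n * (0 + 3 * (R_xlen_t)frame_i)] = st.x[i];
        frames[i + n * (1 + 3 * (R_xlen_t)frame_i)] = st.y[i];
        frames[i + n * (2 + 3 * (R_xlen_t)frame_i)] = st.z[i];
      }
      ++frame_i;
    }
  }

  double eb, es;
  double etot = st.total_energy(&eb, &es);
  NumericMatrix final_coords(n_tails * n_beads, 3);
  for (int i = 0; i < n_tails * n_beads; ++i) {
    final_coords(i, 0) = st.x[i];
    final_coords(i, 1) = st.y[i];
    final_coords(i, 2) = st.z[i];
  }
  return List::create(
      _["frames"] = frames, _["n_frames"] = frame_i,
      _["final_coords"] = final_coords,
      _["energy_bond"] = eb, _["energy_site"] = es, _["energy_total"] = etot,
      _["accept_displacement"] = (double)acc_disp / std::max(try_disp, 1L),
      _["accept_pivot"] = try_piv > 0 ? (double)acc_piv / try_piv : NA_REAL);
}
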