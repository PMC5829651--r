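// Overdamped Langevin engine for a twistable worm-like chain with cohesin
// handcuffs, CTCF obstacles, active/passive swivels and phantom regions.
//
// Geometry/twist bookkeeping: each fibre bond b carries a material angle
// theta[b] and a reference director d[b] perpendicular to the bond tangent.
// Directors are time-parallel-transported (minimal rotation old->new tangent)
// every step; the reference twist m[v] at vertex v (between bonds v-1 and v)
// is the signed angle, about the outgoing tangent, between the space-parallel
// transport of d[v-1] and d[v], unwrapped in time.  The vertex twist
// phi[v] = theta[v] - theta[v-1] + m[v] then satisfies the discrete
// Calugareanu/White identity  sum(phi)/2pi + Wr = Lk  for closed chains.

#include <Rcpp.h>
#include <sstream>
#include <random>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925287;

// ---------------------------------------------------------------- vec utils
static inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1]*b[2] - a[2]*b[1];
  o[1] = a[2]*b[0] - a[0]*b[2];
  o[2] = a[0]*b[1] - a[1]*b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline void scale3(double* a, double s) { a[0]*=s; a[1]*=s; a[2]*=s; }

// rotate v in place by the minimal rotation taking unit vector a to unit b
static void rotate_minimal(const double* a, const double* b, double* v) {
  double k[3];
  cross3(a, b, k);
  double s = norm3(k);
  double c = dot3(a, b);
  if (s < 1e-12) {
    if (c > 0.0) return;                      // no rotation
    // a == -b: rotate by pi about an arbitrary axis perpendicular to a
    double p[3] = {1.0, 0.0, 0.0};
    if (std::fabs(a[0]) > 0.9) { p[0] = 0.0; p[1] = 1.0; }
    double q[3];
    cross3(a, p, q);
    double nq = norm3(q);
    scale3(q, 1.0 / nq);
    double d = dot3(q, v);
    v[0] = 2.0*d*q[0] - v[0];
    v[1] = 2.0*d*q[1] - v[1];
    v[2] = 2.0*d*q[2] - v[2];
    return;
  }
  double k1[3] = {k[0]/s, k[1]/s, k[2]/s};
  double kv[3];
  cross3(k1, v, kv);
  double kdv = dot3(k1, v);
  for (int d = 0; d < 3; ++d)
    v[d] = v[d]*c + kv[d]*s + k1[d]*kdv*(1.0 - c);
}

static inline double signed_angle(const double* u, const double* v,
                                  const double* axis) {
  double c[3];
  cross3(u, v, c);
  return std::atan2(dot3(c, axis), dot3(u, v));
}

// ------------------------------------------------- Klenin-Langowski writhe
// Exact Gauss double integral for one pair of straight segments.
static double segment_pair_omega(const double* p1, const double* p2,
                                 const double* p3, const double* p4) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  for (int d = 0; d < 3; ++d) {
    r12[d] = p2[d] - p1[d];
    r34[d] = p4[d] - p3[d];
    r13[d] = p3[d] - p1[d];
    r14[d] = p4[d] - p1[d];
    r23[d] = p3[d] - p2[d];
    r24[d] = p4[d] - p2[d];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1);
  cross3(r14, r24, n2);
  cross3(r24, r23, n3);
  cross3(r23, r13, n4);
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 < 1e-14 || l2 < 1e-14 || l3 < 1e-14 || l4 < 1e-14) return 0.0;
  scale3(n1, 1.0/l1); scale3(n2, 1.0/l2); scale3(n3, 1.0/l3); scale3(n4, 1.0/l4);
  double a1 = std::asin(std::max(-1.0, std::min(1.0, dot3(n1, n2))));
  double a2 = std::asin(std::max(-1.0, std::min(1.0, dot3(n2, n3))));
  double a3 = std::asin(std::max(-1.0, std::min(1.0, dot3(n3, n4))));
  double a4 = std::asin(std::max(-1.0, std::min(1.0, dot3(n4, n1))));
  double cr[3];
  cross3(r34, r12, cr);
  double sgn = dot3(cr, r13) >= 0.0 ? 1.0 : -1.0;
  return (a1 + a2 + a3 + a4) * sgn;
}

// writhe + per-segment density of a polygonal curve (rows of x are vertices)
static double writhe_polygon(const std::vector<double>& x, int n, bool circular,
                             std::vector<double>* density) {
  int nseg = circular ? n : (n - 1);
  if (density) { density->assign(nseg, 0.0); }
  double wr = 0.0;
  for (int i = 0; i < nseg; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < nseg; ++j) {
      if (circular && i == 0 && j == nseg - 1) continue; // adjacent via wrap
      int j2 = (j + 1) % n;
      double om = segment_pair_omega(&x[3*i], &x[3*i2], &x[3*j], &x[3*j2]);
      double w = om / TWOPI;                 // unordered-pair contribution
      wr += w;
      if (density) {
        (*density)[i] += 0.5 * w;
        (*density)[j] += 0.5 * w;
      }
    }
  }
  return wr;
}

// [[Rcpp::export]]
double cpp_writhe(NumericMatrix x, bool circular) {
  int n = x.nrow();
  std::vector<double> p(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) p[3*i+d] = x(i, d);
  return writhe_polygon(p, n, circular, nullptr);
}

// [[Rcpp::export]]
NumericVector cpp_writhe_density(NumericMatrix x, bool circular) {
  int n = x.nrow();
  std::vector<double> p(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) p[3*i+d] = x(i, d);
  std::vector<double> dens;
  writhe_polygon(p, n, circular, &dens);
  return NumericVector(dens.begin(), dens.end());
}

// [[Rcpp::export]]
double cpp_segment_pair_writhe(NumericVector p1, NumericVector p2,
                               NumericVector p3, NumericVector p4) {
  double a[3] = {p1[0], p1[1], p1[2]}, b[3] = {p2[0], p2[1], p2[2]};
  double c[3] = {p3[0], p3[1], p3[2]}, d[3] = {p4[0], p4[1], p4[2]};
  return segment_pair_omega(a, b, c, d) / TWOPI;
}

// ------------------------------------------------------------- contact map
// [[Rcpp::export]]
NumericMatrix cpp_contact_map(List frames, double cutoff) {
  int nf = frames.size();
  NumericMatrix first = frames[0];
  int n = first.nrow();
  NumericMatrix out(n, n);
  double c2 = cutoff * cutoff;
  for (int f = 0; f < nf; ++f) {
    NumericMatrix fr = frames[f];
    for (int i = 0; i < n; ++i) {
      out(i, i) += 1.0;
      for (int j = i + 1; j < n; ++j) {
        double dx = fr(i,0)-fr(j,0), dy = fr(i,1)-fr(j,1), dz = fr(i,2)-fr(j,2);
        if (dx*dx + dy*dy + dz*dz < c2) { out(i, j) += 1.0; out(j, i) += 1.0; }
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) /= nf;
  return out;
}

// ---------------------------------------------------------- ring threading
// Returns 0-based index of fibre bead threading the ring, or -1.
static int detect_threading(const std::vector<double>& x, int nf,
                            const std::vector<int>& ring,
                            const std::vector<char>& alive,
                            double aperture_r, double plane_tol,
                            double* centre_out, double* normal_out) {
  int nr = (int)ring.size();
  double c[3] = {0, 0, 0};
  for (int k = 0; k < nr; ++k)
    for (int d = 0; d < 3; ++d) c[d] += x[3*ring[k]+d];
  for (int d = 0; d < 3; ++d) c[d] /= nr;
  double nrm[3] = {0, 0, 0};
  for (int k = 0; k < nr; ++k) {
    int a = ring[k], b = ring[(k+1) % nr];
    double u[3] = {x[3*a]-c[0], x[3*a+1]-c[1], x[3*a+2]-c[2]};
    double v[3] = {x[3*b]-c[0], x[3*b+1]-c[1], x[3*b+2]-c[2]};
    double cr[3];
    cross3(u, v, cr);
    for (int d = 0; d < 3; ++d) nrm[d] += cr[d];
  }
  double ln = norm3(nrm);
  if (ln < 1e-12) return -1;
  scale3(nrm, 1.0/ln);
  if (centre_out) for (int d = 0; d < 3; ++d) centre_out[d] = c[d];
  if (normal_out) for (int d = 0; d < 3; ++d) normal_out[d] = nrm[d];
  int best = -1;
  double best_dr = aperture_r;
  for (int i = 0; i < nf; ++i) {
    if (!alive[i]) continue;
    double r[3] = {x[3*i]-c[0], x[3*i+1]-c[1], x[3*i+2]-c[2]};
    double dz = dot3(r, nrm);
    if (std::fabs(dz) > plane_tol) continue;
    double rp[3] = {r[0]-dz*nrm[0], r[1]-dz*nrm[1], r[2]-dz*nrm[2]};
    double dr = norm3(rp);
    if (dr < best_dr) { best_dr = dr; best = i; }   // strict < : lowest index wins ties
  }
  return best;
}

// [[Rcpp::export]]
List cpp_detect_threading(NumericMatrix x, int n_fiber, IntegerVector ring0,
                          double aperture_r, double plane_tol) {
  int n = x.nrow();
  std::vector<double> p(3*n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) p[3*i+d] = x(i, d);
  std::vector<int> ring(ring0.begin(), ring0.end());
  std::vector<char> alive(n, 1);
  double c[3], nrm[3];
  int bead = detect_threading(p, n_fiber, ring, alive, aperture_r, plane_tol,
                              c, nrm);
  return List::create(_["bead"] = bead,
                      _["centre"] = NumericVector::create(c[0], c[1], c[2]),
                      _["normal"] = NumericVector::create(nrm[0], nrm[1], nrm[2]));
}

// ---------------------------------------------------------------- engine
struct ActiveSwivel {
  int vertex;
  double rate;
  int sign;
  bool barrier;
  double injected;
  double target;   // barrier drive: prescribed angle of the driven bond
};

struct Cuff {
  std::vector<int> ringA, ringB;  // global bead indices, 15 each, [0] shared
  int shared;
  bool alive;
  int stateA, stateB;             // 0 active, 1 anchored
  int threadedA, threadedB;       // fibre bead or -1
  double contactA, contactB;      // accumulated divergent contact time
};

struct CtcfSite {
  int bead;     // global index of the obstacle bead
  int attach;   // fibre bead it is tethered to
  int orient;   // +1 convergent, -1 divergent
  bool occupied; // a CTCF C-terminus engages a single ring
};

struct Restraint { int i, j; double r0, k; };
struct Dihedral { int i, j, k, l; double kd, phi0; };  // harmonic about phi0

class Engine {
public:
  // system
  int N, nf, nb;
  bool circular;
  std::vector<double> x;           // 3N
  std::vector<int> species;        // 0 fibre, 1 cohesin, 2 ctcf
  std::vector<double> radius, base_mult, mult;
  std::vector<char> phantom, alive, threaded_bead;
  std::vector<int> cuff_id;        // -1 or cuff index
  std::vector<double> theta, phi0, vertexC, m, m_prev;
  std::vector<char> vertex_passive, vertex_active;
  std::vector<ActiveSwivel> actives;
  std::vector<Cuff> cuffs;
  std::vector<CtcfSite> ctcfs;
  std::vector<Restraint> restraints;
  std::vector<Dihedral> dihedrals;

  // force field
  double l0, k_fene, dmax, k_bend, Ctw, eps_wca, kT;
  // dynamics
  double dt, gamma_t, gamma_r, thread_mult, cuff_mult, max_move, rot_block;
  double contact_dist, dwell, aperture_r, plane_tol;
  int maintain_every, observe_every, nlist_every;
  double skin;
  // state
  double time_now;
  double Lk0;
  bool have_Lk0;
  std::mt19937_64 rng;
  std::normal_distribution<double> gauss;

  // tangents / bond lengths
  std::vector<double> tang, blen, dirs;   // 3*nb, nb, 3*nb
  // forces
  std::vector<double> F, tau, told_buf;
  double lastMinNB;
  // neighbour list: pairs + per-pair sigma
  std::vector<int> nl_i, nl_j;
  std::vector<double> nl_sig;
  // energies of last force pass
  double E_fene, E_bend, E_twist, E_wca, E_restr;
  // events
  std::vector<int> ev_step;
  std::vector<double> ev_time;
  std::vector<std::string> ev_type;
  std::vector<int> ev_cuff, ev_ring, ev_detail;
  long step_count;
  bool blowup;
  std::string blow_msg;

  Engine(List sys, List ctrl, int seed) : gauss(0.0, 1.0) {
    NumericMatrix X = sys["x"];
    N = X.nrow();
    x.resize(3*N);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) x[3*i+d] = X(i, d);
    nf = as<int>(sys["n_fiber"]);
    circular = as<bool>(sys["circular"]);
    nb = circular ? nf : nf - 1;
    species = as<std::vector<int>>(sys["species"]);
    radius = as<std::vector<double>>(sys["radius"]);
    base_mult = as<std::vector<double>>(sys["base_mult"]);
    mult = base_mult;
    {
      LogicalVector ph = sys["phantom"];
      phantom.assign(N, 0);
      for (int i = 0; i < N; ++i) phantom[i] = ph[i] ? 1 : 0;
    }
    cuff_id = as<std::vector<int>>(sys["cuff_id"]);
    alive.assign(N, 1);
    theta = as<std::vector<double>>(sys["theta"]);
    phi0 = as<std::vector<double>>(sys["phi0"]);
    {
      LogicalVector pv = sys["vertex_passive"];
      vertex_passive.assign(nb, 0);
      for (int v = 0; v < nb; ++v) vertex_passive[v] = pv[v] ? 1 : 0;
    }
    vertex_active.assign(nb, 0);
    List act = sys["actives"];
    for (int a = 0; a < act.size(); ++a) {
      List A = act[a];
      ActiveSwivel s;
      s.vertex = as<int>(A["vertex"]);
      s.rate = as<double>(A["rate"]);
      s.sign = as<int>(A["sign"]);
      s.barrier = as<bool>(A["barrier"]);
      s.injected = as<double>(A["injected"]);
      actives.push_back(s);
      vertex_active[s.vertex] = 1;
    }
    List cfs = sys["cuffs"];
    for (int c = 0; c < cfs.size(); ++c) {
      List C = cfs[c];
      Cuff k;
      k.ringA = as<std::vector<int>>(C["ring_a"]);
      k.ringB = as<std::vector<int>>(C["ring_b"]);
      k.shared = as<int>(C["shared"]);
      k.alive = as<bool>(C["alive"]);
      k.stateA = as<int>(C["state_a"]);
      k.stateB = as<int>(C["state_b"]);
      k.threadedA = as<int>(C["threaded_a"]);
      k.threadedB = as<int>(C["threaded_b"]);
      k.contactA = k.contactB = 0.0;
      cuffs.push_back(k);
      if (!k.alive) killCuff(c, false);
    }
    List cts = sys["ctcf"];
    for (int c = 0; c < cts.size(); ++c) {
      List C = cts[c];
      CtcfSite s;
      s.bead = as<int>(C["bead"]);
      s.attach = as<int>(C["attach"]);
      s.orient = as<int>(C["orient"]);
      s.occupied = false;
      ctcfs.push_back(s);
    }
    NumericMatrix R = sys["restraints"];
    for (int r = 0; r < R.nrow(); ++r)
      restraints.push_back({(int)R(r,0), (int)R(r,1), R(r,2), R(r,3)});
    if (sys.containsElementNamed("dihedrals") && !Rf_isNull(sys["dihedrals"])) {
      NumericMatrix D = sys["dihedrals"];
      for (int r = 0; r < D.nrow(); ++r)
        dihedrals.push_back({(int)D(r,0), (int)D(r,1), (int)D(r,2),
                             (int)D(r,3), D(r,4), D(r,5)});
    }

    List ff = sys["ff"];
    l0 = as<double>(ff["l0"]);
    k_fene = as<double>(ff["k_fene"]);
    dmax = as<double>(ff["r_fene_max"]) - l0;
    k_bend = as<double>(ff["k_bend"]);
    Ctw = as<double>(ff["C"]);
    eps_wca = as<double>(ff["eps_wca"]);
    kT = as<double>(ff["kT"]);

    dt = as<double>(ctrl["dt"]);
    gamma_t = as<double>(ctrl["gamma_t"]);
    gamma_r = as<double>(ctrl["gamma_r"]);
    thread_mult = as<double>(ctrl["thread_mult"]);
    cuff_mult = as<double>(ctrl["cuff_mult"]);
    contact_dist = as<double>(ctrl["contact_dist"]);
    dwell = as<double>(ctrl["dwell"]);
    aperture_r = as<double>(ctrl["aperture_r"]);
    plane_tol = as<double>(ctrl["plane_tol"]);
    maintain_every = as<int>(ctrl["maintain_every"]);
    observe_every = as<int>(ctrl["observe_every"]);
    nlist_every = as<int>(ctrl["nlist_every"]);
    skin = as<double>(ctrl["skin"]);
    max_move = as<double>(ctrl["max_move"]);
    rot_block = as<double>(ctrl["rot_block"]);
    time_now = as<double>(ctrl["time0"]);
    kTtemp = as<double>(ctrl["temperature"]);

    rng.seed((uint64_t)seed);
    step_count = 0;
    blowup = false;
    lastMinNB = NA_REAL;

    tang.resize(3*nb);
    blen.resize(nb);
    dirs.resize(3*nb);
    m.assign(nb, 0.0);
    F.resize(3*N);
    tau.resize(nb);
    vertexC.assign(nb, Ctw);
    for (int v = 0; v < nb; ++v) {
      if (vertex_passive[v]) vertexC[v] = 0.0;
    }
    for (auto& s : actives)
      if (s.barrier) {
        // the joint transmits nothing; the polymerase is externally braced
        // and prescribes the rotation of the bond behind it (stiff tracking
        // spring), so injection feeds the lower-index flank only
        vertexC[s.vertex] = 0.0;
        s.target = theta[bondPrev(s.vertex)];
      }

    updateTangents();
    initFrames(sys);
    computeRefTwist(true);
    // continuation: restore the unwrapped branch of the reference twist
    if (sys.containsElementNamed("m0") && !Rf_isNull(sys["m0"])) {
      NumericVector m0 = sys["m0"];
      for (int v = vfirst(); v < nb; ++v)
        m[v] += TWOPI * std::round((m0[v] - m[v]) / TWOPI);
      m_prev = m;
    }
    buildNeighbourList();
    applyDragRules();
    have_Lk0 = sys.containsElementNamed("Lk0") &&
               !Rf_isNull(sys["Lk0"]);
    if (have_Lk0) Lk0 = as<double>(sys["Lk0"]);
    else Lk0 = twTransmitting() + writheFibre(nullptr);
  }

  double kTtemp;   // simulation temperature (kT units); kT above is the unit

  int vfirst() const { return circular ? 0 : 1; }
  int bondPrev(int v) const { return circular ? (v - 1 + nb) % nb : v - 1; }
  int beadNext(int i) const { return circular ? (i + 1) % nf : i + 1; }

  void updateTangents() {
    for (int b = 0; b < nb; ++b) {
      int i = b, j = beadNext(b);
      double e[3] = {x[3*j]-x[3*i], x[3*j+1]-x[3*i+1], x[3*j+2]-x[3*i+2]};
      double L = norm3(e);
      blen[b] = L;
      for (int d = 0; d < 3; ++d) tang[3*b+d] = e[d] / L;
    }
  }

  void initFrames(List sys) {
    if (sys.containsElementNamed("dirs") && !Rf_isNull(sys["dirs"])) {
      NumericMatrix D = sys["dirs"];
      for (int b = 0; b < nb; ++b)
        for (int d = 0; d < 3; ++d) dirs[3*b+d] = D(b, d);
      return;
    }
    // first director: any unit vector perpendicular to tangent 0
    double t0[3] = {tang[0], tang[1], tang[2]};
    double ref[3] = {0.0, 0.0, 1.0};
    if (std::fabs(t0[2]) > 0.9) { ref[2] = 0.0; ref[0] = 1.0; }
    double d0[3];
    cross3(t0, ref, d0);
    scale3(d0, 1.0 / norm3(d0));
    for (int d = 0; d < 3; ++d) dirs[d] = d0[d];
    // space-parallel transport along the chain
    for (int b = 1; b < nb; ++b) {
      double v[3] = {dirs[3*(b-1)], dirs[3*(b-1)+1], dirs[3*(b-1)+2]};
      rotate_minimal(&tang[3*(b-1)], &tang[3*b], v);
      // orthonormalize against tangent
      double pr = dot3(v, &tang[3*b]);
      for (int d = 0; d < 3; ++d) v[d] -= pr * tang[3*b+d];
      scale3(v, 1.0 / norm3(v));
      for (int d = 0; d < 3; ++d) dirs[3*b+d] = v[d];
    }
  }

  void computeRefTwist(bool init) {
    for (int v = vfirst(); v < nb; ++v) {
      int bp = bondPrev(v);
      double dprev[3] = {dirs[3*bp], dirs[3*bp+1], dirs[3*bp+2]};
      rotate_minimal(&tang[3*bp], &tang[3*v], dprev);
      double raw = signed_angle(dprev, &dirs[3*v], &tang[3*v]);
      if (init) m[v] = raw;
      else m[v] = raw + TWOPI * std::round((m_prev[v] - raw) / TWOPI);
    }
    m_prev = m;
  }

  double vertexPhi(int v) const {
    return theta[v] - theta[bondPrev(v)] + m[v];
  }

  double twTransmitting() const {
    double s = 0.0;
    for (int v = vfirst(); v < nb; ++v)
      if (vertexC[v] > 0.0 && !vertex_active[v]) s += vertexPhi(v);
    return s / TWOPI;
  }

  double twFree() const {
    double s = 0.0;
    for (int v = vfirst(); v < nb; ++v)
      if (!(vertexC[v] > 0.0) || vertex_active[v]) s += vertexPhi(v);
    return s / TWOPI;
  }

  double writheFibre(std::vector<double>* density) const {
    std::vector<double> p(x.begin(), x.begin() + 3*nf);
    return writhe_polygon(p, nf, circular, density);
  }

  // ------------------------------------------------------------- WCA pairs
  bool pairExcluded(int i, int j) const {
    if (!alive[i] || !alive[j]) return true;
    int si = species[i], sj = species[j];
    if (si == 0 && sj == 0) {
      if (phantom[i] || phantom[j]) return true;
      int lo = std::min(i, j), hi = std::max(i, j);
      if (hi - lo == 1) return true;
      if (circular && lo == 0 && hi == nf - 1) return true;
      return false;
    }
    if (si == 1 && sj == 1 && cuff_id[i] == cuff_id[j]) return true;
    if (si == 2 || sj == 2) {
      int cb = (si == 2) ? i : j;
      int ob = (si == 2) ? j : i;
      if (species[ob] == 0) {
        int attach = -1;
        for (const auto& c : ctcfs) if (c.bead == cb) { attach = c.attach; break; }
        if (attach >= 0) {
          int dd = std::abs(ob - attach);
          if (circular) dd = std::min(dd, nf - dd);
          if (dd <= 2) return true;
        }
      }
    }
    return false;
  }

  void buildNeighbourList() {
    nl_i.clear(); nl_j.clear(); nl_sig.clear();
    double maxr = 0.0;
    for (int i = 0; i < N; ++i) maxr = std::max(maxr, radius[i]);
    double rc = 2.0 * maxr * 1.122462048309373 + skin;
    double rc2 = rc * rc;
    for (int i = 0; i < N; ++i) {
      if (!alive[i]) continue;
      for (int j = i + 1; j < N; ++j) {
        if (!alive[j]) continue;
        double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
        if (dx*dx + dy*dy + dz*dz > rc2) continue;
        if (pairExcluded(i, j)) continue;
        nl_i.push_back(i);
        nl_j.push_back(j);
        nl_sig.push_back(radius[i] + radius[j]);
      }
    }
  }

  // ------------------------------------------------------------- forces
  void computeForces() {
    std::fill(F.begin(), F.end(), 0.0);
    std::fill(tau.begin(), tau.end(), 0.0);
    E_fene = E_bend = E_twist = E_wca = E_restr = 0.0;

    // FENE bonds along the fibre
    for (int b = 0; b < nb; ++b) {
      int i = b, j = beadNext(b);
      double r = blen[b];
      double u = (r - l0) / dmax;
      if (u*u >= 0.9801) {
        blowup = true;
        std::ostringstream ss;
        ss << "bond over-extension (integration blow-up): bond " << b
           << " length " << r << " sigma at step " << step_count
           << "; reduce dt";
        blow_msg = ss.str();
        return;
      }
      E_fene += -0.5 * k_fene * dmax * dmax * std::log(1.0 - u*u);
      double fr = -k_fene * (r - l0) / (1.0 - u*u);   // dE/dr with sign: F = fr * ehat on j
      for (int d = 0; d < 3; ++d) {
        double f = fr * tang[3*b+d];
        F[3*j+d] += f;
        F[3*i+d] -= f;
      }
    }
    if (blowup) return;

    // bending + twist at fibre vertices
    for (int v = vfirst(); v < nb; ++v) {
      int bp = bondPrev(v);
      int im = circular ? (v - 1 + nf) % nf : v - 1;
      int ip = beadNext(v);
      const double* t0 = &tang[3*bp];
      const double* t1 = &tang[3*v];
      double c = std::max(-1.0, std::min(1.0, dot3(t0, t1)));
      double th = std::acos(c);
      E_bend += 0.5 * k_bend * th * th;
      double s = std::sqrt(std::max(1e-16, 1.0 - c*c));
      double fac = (th < 1e-6) ? k_bend : k_bend * th / s;   // -dE/dcos * (-1): see below
      // dcos/de0 = (t1 - c t0)/L0 ; dcos/de1 = (t0 - c t1)/L1
      double g0[3], g1[3];
      for (int d = 0; d < 3; ++d) {
        g0[d] = (t1[d] - c*t0[d]) / blen[bp];
        g1[d] = (t0[d] - c*t1[d]) / blen[v];
      }
      // E = 0.5 k th^2, dE/dcos = -k th / s ; F = -dE/dx = (k th/s) dcos/dx
      for (int d = 0; d < 3; ++d) {
        F[3*im+d] += fac * (-g0[d]);
        F[3*v+d]  += fac * (g0[d] - g1[d]);
        F[3*ip+d] += fac * (g1[d]);
      }

      if (vertexC[v] > 0.0) {
        double dphi = vertexPhi(v) - phi0[v];
        E_twist += 0.5 * (vertexC[v] / l0) * dphi * dphi;
        double coef = (vertexC[v] / l0) * dphi;
        // torques on material angles
        tau[v]  -= coef;
        tau[bp] += coef;
        // twist-bend coupling force: grad of reference twist m[v]
        double kb[3];
        cross3(t0, t1, kb);
        double den = 1.0 + c;
        for (int d = 0; d < 3; ++d) kb[d] *= 2.0 / den;
        // grad of the reference twist with respect to bead positions
        // (curvature-binormal form; sign fixed by the orientation of m:
        // validated against zero-temperature relaxation of a twisted ring)
        for (int d = 0; d < 3; ++d) {
          double gm_m = -kb[d] / (2.0 * blen[bp]);
          double gm_p = kb[d] / (2.0 * blen[v]);
          F[3*im+d] -= coef * gm_m;
          F[3*ip+d] -= coef * gm_p;
          F[3*v+d]  -= coef * (-(gm_m + gm_p));
        }
      }
    }

    // WCA excluded volume
    double minnb = R_PosInf;
    for (size_t p = 0; p < nl_i.size(); ++p) {
      int i = nl_i[p], j = nl_j[p];
      double dx = x[3*i]-x[3*j], dy = x[3*i+1]-x[3*j+1], dz = x[3*i+2]-x[3*j+2];
      double r2 = dx*dx + dy*dy + dz*dz;
      double r = std::sqrt(r2);
      if (r < minnb) minnb = r;
      double sig = nl_sig[p];
      double rc2 = sig * sig * 1.2599210498948732;   // (2^{1/6} sig)^2
      if (r2 >= rc2) continue;
      double sr2 = sig*sig / r2;
      double sr6 = sr2 * sr2 * sr2;
      double sr12 = sr6 * sr6;
      E_wca += 4.0 * eps_wca * (sr12 - sr6) + eps_wca;
      double fmag = 24.0 * eps_wca * (2.0*sr12 - sr6) / r2;   // F = fmag * rvec on i
      F[3*i]   += fmag * dx;
      F[3*i+1] += fmag * dy;
      F[3*i+2] += fmag * dz;
      F[3*j]   -= fmag * dx;
      F[3*j+1] -= fmag * dy;
      F[3*j+2] -= fmag * dz;
    }
    lastMinNB = minnb;

    // harmonic restraints (handcuff network, CTCF tethers, anchors)
    for (const auto& rs : restraints) {
      if (!alive[rs.i] || !alive[rs.j]) continue;
      double dx = x[3*rs.i]-x[3*rs.j], dy = x[3*rs.i+1]-x[3*rs.j+1],
             dz = x[3*rs.i+2]-x[3*rs.j+2];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < 1e-12) continue;
      double dr = r - rs.r0;
      E_restr += 0.5 * rs.k * dr * dr;
      double fmag = -rs.k * dr / r;
      F[3*rs.i]   += fmag * dx;
      F[3*rs.i+1] += fmag * dy;
      F[3*rs.i+2] += fmag * dz;
      F[3*rs.j]   -= fmag * dx;
      F[3*rs.j+1] -= fmag * dy;
      F[3*rs.j+2] -= fmag * dz;
    }

    // planarity (dihedral) restraints of the handcuff rings: harmonic in the
    // signed dihedral angle about zero, standard four-body gradient
    for (const auto& dh : dihedrals) {
      if (!alive[dh.i] || !alive[dh.j] || !alive[dh.k] || !alive[dh.l])
        continue;
      double b1[3], b2[3], b3[3];
      for (int d = 0; d < 3; ++d) {
        b1[d] = x[3*dh.j+d] - x[3*dh.i+d];
        b2[d] = x[3*dh.k+d] - x[3*dh.j+d];
        b3[d] = x[3*dh.l+d] - x[3*dh.k+d];
      }
      double n1[3], n2[3];
      cross3(b1, b2, n1);
      cross3(b2, b3, n2);
      double ln1 = dot3(n1, n1), ln2 = dot3(n2, n2);
      double lb2 = norm3(b2);
      if (ln1 < 1e-16 || ln2 < 1e-16 || lb2 < 1e-12) continue;
      double cx[3];
      cross3(n1, n2, cx);
      double phi = std::atan2(dot3(cx, b2) / lb2, dot3(n1, n2));
      double dphi = phi - dh.phi0;
      dphi -= TWOPI * std::round(dphi / TWOPI);
      E_restr += 0.5 * dh.kd * dphi * dphi;
      double coef = -dh.kd * dphi;            // force = coef * dphi/dx
      double gi[3], gl[3], gj[3], gk[3];
      double c12 = dot3(b1, b2) / (lb2 * lb2);
      double c32 = dot3(b3, b2) / (lb2 * lb2);
      for (int d = 0; d < 3; ++d) {
        gi[d] = -lb2 / ln1 * n1[d];
        gl[d] =  lb2 / ln2 * n2[d];
        gj[d] = (-1.0 - c12) * gi[d] + c32 * gl[d];
        gk[d] = c12 * gi[d] + (-1.0 - c32) * gl[d];
      }
      for (int d = 0; d < 3; ++d) {
        F[3*dh.i+d] += coef * gi[d];
        F[3*dh.j+d] += coef * gj[d];
        F[3*dh.k+d] += coef * gk[d];
        F[3*dh.l+d] += coef * gl[d];
      }
    }
  }

  // ------------------------------------------------------------ drag rules
  void applyDragRules() {
    mult = base_mult;
    threaded_bead.assign(N, 0);
    auto blockAround = [&](int b) {
      // the ring body spans a few beads of fibre: keep the crankshaft block
      // continuous under +-1-bead flicker of the threading detector
      for (int d = -2; d <= 2; ++d) {
        int k = b + d;
        if (circular) k = (k % nf + nf) % nf;
        if (k >= 0 && k < nf) threaded_bead[k] = 1;
      }
    };
    for (auto& c : cuffs) {
      if (!c.alive) continue;
      if (c.threadedA >= 0) { mult[c.threadedA] = thread_mult; blockAround(c.threadedA); }
      if (c.threadedB >= 0) { mult[c.threadedB] = thread_mult; blockAround(c.threadedB); }
    }
  }

  void killCuff(int ci, bool log) {
    Cuff& c = cuffs[ci];
    c.alive = false;
    for (int b : c.ringA) alive[b] = 0;
    for (int b : c.ringB) alive[b] = 0;
    c.threadedA = c.threadedB = -1;
    if (log) pushEvent("dissociated", ci, -1, -1);
  }

  void pushEvent(const std::string& type, int cuff, int ring, int detail) {
    ev_step.push_back((int)step_count);
    ev_time.push_back(time_now);
    ev_type.push_back(type);
    ev_cuff.push_back(cuff);
    ev_ring.push_back(ring);
    ev_detail.push_back(detail);
  }

  void maintenance() {
    // threading detection per ring (the +-2-bead smear of the conduction
    // block in applyDragRules absorbs frame-to-frame flicker of the
    // nearest-bead choice)
    for (size_t ci = 0; ci < cuffs.size(); ++ci) {
      Cuff& c = cuffs[ci];
      if (!c.alive) continue;
      for (int ring = 0; ring < 2; ++ring) {
        std::vector<int>& rg = ring == 0 ? c.ringA : c.ringB;
        int& thr = ring == 0 ? c.threadedA : c.threadedB;
        int nb_new = detect_threading(x, nf, rg, alive, aperture_r, plane_tol,
                                      nullptr, nullptr);
        if (nb_new < 0 && thr >= 0) pushEvent("unthreaded", (int)ci, ring, thr);
        if (nb_new >= 0 && thr < 0) pushEvent("threaded", (int)ci, ring, nb_new);
        thr = nb_new;
      }
    }
    applyDragRules();

    // CTCF anchor / dissociate rule
    double block_dt = maintain_every * dt;
    for (size_t ci = 0; ci < cuffs.size(); ++ci) {
      Cuff& c = cuffs[ci];
      if (!c.alive) continue;
      for (int ring = 0; ring < 2; ++ring) {
        std::vector<int>& rg = ring == 0 ? c.ringA : c.ringB;
        int& st = ring == 0 ? c.stateA : c.stateB;
        double& ct = ring == 0 ? c.contactA : c.contactB;
        double cc[3] = {0, 0, 0};
        for (int b : rg) for (int d = 0; d < 3; ++d) cc[d] += x[3*b+d];
        for (int d = 0; d < 3; ++d) cc[d] /= rg.size();
        bool contact = false;
        for (auto& s : ctcfs) {
          double dx = cc[0]-x[3*s.bead], dy = cc[1]-x[3*s.bead+1],
                 dz = cc[2]-x[3*s.bead+2];
          double dd = std::sqrt(dx*dx + dy*dy + dz*dz);
          if (dd < contact_dist) {
            contact = true;
            if (s.orient > 0 && !s.occupied) {
              if (st == 0) {
                // anchor: tether the 3 ring beads nearest the obstacle
                std::vector<std::pair<double,int>> near;
                for (int b : rg) {
                  double ex = x[3*b]-x[3*s.bead], ey = x[3*b+1]-x[3*s.bead+1],
                         ez = x[3*b+2]-x[3*s.bead+2];
                  near.push_back({std::sqrt(ex*ex+ey*ey+ez*ez), b});
                }
                std::sort(near.begin(), near.end());
                for (int q = 0; q < 3; ++q)
                  restraints.push_back({near[q].second, s.bead, near[q].first, 30.0});
                st = 1;
                s.occupied = true;
                pushEvent("anchored", (int)ci, ring, s.attach);
              }
            }
          }
        }
        bool div_contact = false;
        for (const auto& s : ctcfs) {
          if (s.orient >= 0) continue;   // convergent or neutral obstacle
          double dx = cc[0]-x[3*s.bead], dy = cc[1]-x[3*s.bead+1],
                 dz = cc[2]-x[3*s.bead+2];
          if (std::sqrt(dx*dx + dy*dy + dz*dz) < contact_dist) div_contact = true;
        }
        if (div_contact) {
          ct += block_dt;
          if (ct >= dwell) { killCuff((int)ci, true); break; }
        } else ct = 0.0;
        (void)contact;
      }
    }
    buildNeighbourList();
  }

  // --------------------------------------------------------------- stepping
  void step() {
    computeForces();
    if (blowup) return;
    // externally braced barrier drives: stiff spring pulling the driven
    // bond's material angle along the prescribed rotation
    for (auto& s : actives)
      if (s.barrier) {
        int b = bondPrev(s.vertex);
        tau[b] += -10.0 * (Ctw / l0) * (theta[b] - s.target);
      }
    told_buf = tang;
    const std::vector<double>& told = told_buf;
    double noise_scale = std::sqrt(2.0 * kTtemp * dt);
    // cap the deterministic displacement per step: inside the steep FENE/WCA
    // walls the local stiffness exceeds 2*gamma/dt and the explicit update
    // would amplify oscillations; the cap (default 0.25 sigma) is inactive
    // everywhere forces are moderate and only tames the divergent walls.
    for (int i = 0; i < N; ++i) {
      if (!alive[i]) continue;
      double g = gamma_t * mult[i];
      double amp = noise_scale / std::sqrt(g);
      double dx[3];
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) { dx[d] = F[3*i+d] * dt / g; d2 += dx[d]*dx[d]; }
      if (d2 > max_move * max_move) {
        double sc = max_move / std::sqrt(d2);
        for (int d = 0; d < 3; ++d) dx[d] *= sc;
      }
      for (int d = 0; d < 3; ++d)
        x[3*i+d] += dx[d] + amp * gauss(rng);
    }
    for (int b = 0; b < nb; ++b) {
      int i = b, j = beadNext(b);
      // twist conduction through a threading ring is sterically blocked:
      // bonds touching a threaded bead get the rot_block rotational factor
      double g = gamma_r * std::max(mult[i], mult[j]);
      if (threaded_bead[i] || threaded_bead[j]) g = gamma_r * rot_block;
      double amp = noise_scale / std::sqrt(g);
      double dth = tau[b] * dt / g;
      if (dth > 0.5) dth = 0.5; else if (dth < -0.5) dth = -0.5;
      theta[b] += dth + amp * gauss(rng);
    }
    updateTangents();
    // time-parallel transport of reference directors
    for (int b = 0; b < nb; ++b) {
      double v[3] = {dirs[3*b], dirs[3*b+1], dirs[3*b+2]};
      rotate_minimal(&told[3*b], &tang[3*b], v);
      double pr = dot3(v, &tang[3*b]);
      for (int d = 0; d < 3; ++d) v[d] -= pr * tang[3*b+d];
      double nv = norm3(v);
      scale3(v, 1.0 / nv);
      for (int d = 0; d < 3; ++d) dirs[3*b+d] = v[d];
    }
    computeRefTwist(false);
    // advance active swivels
    for (auto& s : actives) {
      if (s.barrier) s.target += s.sign * TWOPI * s.rate * dt;
      else phi0[s.vertex] += -s.sign * TWOPI * s.rate * dt;
      s.injected += s.rate * dt;
    }
    time_now += dt;
    ++step_count;
  }

  double maxInjected() const {
    double m = 0.0;
    for (const auto& s : actives) m = std::max(m, s.injected);
    return m;
  }

  int loopExtent(const Cuff& c, int swivel_bead) const {
    if (!c.alive || c.threadedA < 0 || c.threadedB < 0) return NA_INTEGER;
    int a = c.threadedA, b = c.threadedB;
    if (a == b) return 0;
    int lo = std::min(a, b), hi = std::max(a, b);
    if (!circular) return hi - lo;
    // choose the arc containing the swivel bead
    bool in_mid = (swivel_bead > lo && swivel_bead < hi);
    return in_mid ? (hi - lo) : (nf - (hi - lo));
  }

  double enclosedWr(const Cuff& c, int swivel_bead,
                    const std::vector<double>& dens) const {
    if (!c.alive || c.threadedA < 0 || c.threadedB < 0) return NA_REAL;
    int a = c.threadedA, b = c.threadedB;
    int lo = std::min(a, b), hi = std::max(a, b);
    double s = 0.0;
    if (!circular || (swivel_bead > lo && swivel_bead < hi)) {
      for (int i = lo; i < hi && i < (int)dens.size(); ++i) s += dens[i];
    } else {
      for (int i = hi; i < (int)dens.size(); ++i) s += dens[i];
      for (int i = 0; i < lo; ++i) s += dens[i];
    }
    return s;
  }
};

// ------------------------------------------------------------------ wrappers

static List engine_state(Engine& E) {
  NumericMatrix X(E.N, 3);
  for (int i = 0; i < E.N; ++i)
    for (int d = 0; d < 3; ++d) X(i, d) = E.x[3*i+d];
  NumericMatrix D(E.nb, 3);
  for (int b = 0; b < E.nb; ++b)
    for (int d = 0; d < 3; ++d) D(b, d) = E.dirs[3*b+d];
  List cuffs(E.cuffs.size());
  for (size_t c = 0; c < E.cuffs.size(); ++c) {
    const Cuff& k = E.cuffs[c];
    cuffs[c] = List::create(
      _["alive"] = k.alive, _["state_a"] = k.stateA, _["state_b"] = k.stateB,
      _["threaded_a"] = k.threadedA, _["threaded_b"] = k.threadedB);
  }
  NumericVector inj(E.actives.size());
  for (size_t a = 0; a < E.actives.size(); ++a) inj[a] = E.actives[a].injected;
  return List::create(
    _["x"] = X, _["theta"] = NumericVector(E.theta.begin(), E.theta.end()),
    _["phi0"] = NumericVector(E.phi0.begin(), E.phi0.end()),
    _["dirs"] = D, _["m"] = NumericVector(E.m.begin(), E.m.end()),
    _["mult"] = NumericVector(E.mult.begin(), E.mult.end()),
    _["injected"] = inj, _["cuffs"] = cuffs, _["time"] = E.time_now,
    _["Lk0"] = E.Lk0);
}

// single force/energy evaluation (used by tests and energy reporting)
// [[Rcpp::export]]
List cpp_forces(List sys, List ctrl) {
  Engine E(sys, ctrl, 1);
  E.computeForces();
  if (E.blowup) stop(E.blow_msg);
  NumericMatrix Fm(E.N, 3);
  for (int i = 0; i < E.N; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = E.F[3*i+d];
  NumericVector phi(E.nb);
  for (int v = 0; v < E.nb; ++v)
    phi[v] = (v >= E.vfirst()) ? E.vertexPhi(v) : NA_REAL;
  return List::create(
    _["F"] = Fm, _["tau"] = NumericVector(E.tau.begin(), E.tau.end()),
    _["phi"] = phi, _["m"] = NumericVector(E.m.begin(), E.m.end()),
    _["energy"] = List::create(
      _["fene"] = E.E_fene, _["bend"] = E.E_bend, _["twist"] = E.E_twist,
      _["wca"] = E.E_wca, _["restraint"] = E.E_restr,
      _["total"] = E.E_fene + E.E_bend + E.E_twist + E.E_wca + E.E_restr),
    _["min_nonbonded"] = E.lastMinNB,
    _["tw_transmitting"] = E.twTransmitting(),
    _["tw_free"] = E.twFree(),
    _["Lk0"] = E.Lk0,
    _["drag_mult"] = NumericVector(E.mult.begin(), E.mult.end()));
}

// [[Rcpp::export]]
List cpp_run(List sys, List ctrl, int seed) {
  Engine E(sys, ctrl, seed);
  long n_steps = (long)as<double>(ctrl["n_steps"]);
  double stop_R = as<double>(ctrl["stop_R"]);       // <= 0: ignore
  bool record_frames = as<bool>(ctrl["record_frames"]);
  bool stop_diss = as<bool>(ctrl["stop_on_dissociation"]);
  bool record_profile = as<bool>(ctrl["record_profile"]);
  int swivel_bead = E.actives.empty() ? 0 : E.actives[0].vertex;

  std::vector<double> ob_time, ob_tw, ob_twfree, ob_wr, ob_lkdef, ob_inj,
      ob_loop, ob_encwr, ob_minnb, ob_energy, ob_etwist;
  std::vector<int> ob_thra, ob_thrb, ob_step;
  List frames;
  List profiles;
  std::vector<NumericMatrix> frame_store;
  std::vector<NumericVector> prof_store;

  auto observe = [&]() {
    std::vector<double> dens;
    double wr = E.writheFibre(&dens);
    E.computeForces();                      // current energies at this frame
    if (E.blowup) stop(E.blow_msg);
    ob_energy.push_back(E.E_fene + E.E_bend + E.E_twist + E.E_wca + E.E_restr);
    ob_etwist.push_back(E.E_twist);
    double tw = E.twTransmitting();
    double sgnR = 0.0;
    for (const auto& s : E.actives) sgnR += s.sign * s.injected;
    ob_step.push_back((int)E.step_count);
    ob_time.push_back(E.time_now);
    ob_tw.push_back(tw);
    ob_twfree.push_back(E.twFree());
    ob_wr.push_back(wr);
    ob_lkdef.push_back(tw + wr - E.Lk0 - sgnR);
    ob_inj.push_back(E.maxInjected());
    ob_minnb.push_back(E.lastMinNB);
    if (!E.cuffs.empty()) {
      const Cuff& c = E.cuffs[0];
      ob_thra.push_back(c.threadedA);
      ob_thrb.push_back(c.threadedB);
      int le = E.loopExtent(c, swivel_bead);
      ob_loop.push_back(le == NA_INTEGER ? NA_REAL : (double)le);
      ob_encwr.push_back(E.enclosedWr(c, swivel_bead, dens));
    } else {
      ob_thra.push_back(NA_INTEGER);
      ob_thrb.push_back(NA_INTEGER);
      ob_loop.push_back(NA_REAL);
      ob_encwr.push_back(NA_REAL);
    }
    if (record_frames) {
      NumericMatrix X(E.N, 3);
      for (int i = 0; i < E.N; ++i)
        for (int d = 0; d < 3; ++d) X(i, d) = E.x[3*i+d];
      frame_store.push_back(X);
    }
    if (record_profile)
      prof_store.push_back(NumericVector(dens.begin(), dens.end()));
  };

  E.maintenance();
  observe();                                   // initial frame
  long steps_done = 0;
  while (steps_done < n_steps) {
    E.step();
    if (E.blowup) stop(E.blow_msg);
    ++steps_done;
    if (E.step_count % E.maintain_every == 0) E.maintenance();
    else if (E.step_count % E.nlist_every == 0) E.buildNeighbourList();
    if (E.step_count % E.observe_every == 0) observe();
    if (stop_R > 0 && E.maxInjected() >= stop_R) {
      if (E.step_count % E.observe_every != 0) observe();
      break;
    }
    if (stop_diss && !E.cuffs.empty()) {
      bool any_alive = false;
      for (const auto& c : E.cuffs) if (c.alive) any_alive = true;
      if (!any_alive) {
        if (E.step_count % E.observe_every != 0) observe();
        break;
      }
    }
    if (steps_done % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_steps == 0 || (ob_step.back() != (int)E.step_count)) {
    if (n_steps > 0) observe();
  }

  int no = (int)ob_time.size();
  List obs = List::create(
    _["step"] = IntegerVector(ob_step.begin(), ob_step.end()),
    _["time"] = NumericVector(ob_time.begin(), ob_time.end()),
    _["Tw"] = NumericVector(ob_tw.begin(), ob_tw.end()),
    _["Tw_free"] = NumericVector(ob_twfree.begin(), ob_twfree.end()),
    _["Wr"] = NumericVector(ob_wr.begin(), ob_wr.end()),
    _["lk_deficit"] = NumericVector(ob_lkdef.begin(), ob_lkdef.end()),
    _["injected_R"] = NumericVector(ob_inj.begin(), ob_inj.end()),
    _["threaded_a"] = IntegerVector(ob_thra.begin(), ob_thra.end()),
    _["threaded_b"] = IntegerVector(ob_thrb.begin(), ob_thrb.end()),
    _["loop_extent"] = NumericVector(ob_loop.begin(), ob_loop.end()),
    _["enclosed_Wr"] = NumericVector(ob_encwr.begin(), ob_encwr.end()),
    _["min_nonbonded"] = NumericVector(ob_minnb.begin(), ob_minnb.end()),
    _["energy"] = NumericVector(ob_energy.begin(), ob_energy.end()),
    _["twist_energy"] = NumericVector(ob_etwist.begin(), ob_etwist.end()));

  List fr(frame_store.size());
  for (size_t i = 0; i < frame_store.size(); ++i) fr[i] = frame_store[i];
  List pf(prof_store.size());
  for (size_t i = 0; i < prof_store.size(); ++i) pf[i] = prof_store[i];

  DataFrame events = DataFrame::create(
    _["step"] = IntegerVector(E.ev_step.begin(), E.ev_step.end()),
    _["time"] = NumericVector(E.ev_time.begin(), E.ev_time.end()),
    _["type"] = CharacterVector(E.ev_type.begin(), E.ev_type.end()),
    _["cuff"] = IntegerVector(E.ev_cuff.begin(), E.ev_cuff.end()),
    _["ring"] = IntegerVector(E.ev_ring.begin(), E.ev_ring.end()),
    _["detail"] = IntegerVector(E.ev_detail.begin(), E.ev_detail.end()),
    _["stringsAsFactors"] = false);

  (void)no;
  return List::create(
    _["obs"] = obs, _["frames"] = fr, _["profiles"] = pf,
    _["events"] = events, _["final"] = engine_state(E),
    _["n_steps_done"] = (double)steps_done);
}
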