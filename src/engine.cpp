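// Minimal CG molecular dynamics engine: harmonic bonds + truncated,
// potential-shifted Lennard-Jones, steepest-descent minimization, and
// velocity-Verlet / BAOAB-Langevin / stochastic-velocity-rescale dynamics.
//
// Internal units are the usual consistent MD set: nm, ps, amu, kJ/mol
// (so force is kJ mol^-1 nm^-1 and acceleration nm ps^-2).  All randomness
// is drawn from R's RNG, so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double KB = 0.0083144621;  // kJ/mol/K

struct System {
  int n;
  std::vector<double> x;           // 3n positions, nm
  std::vector<int> bi, bj;         // bonds, 0-based
  std::vector<double> r0, bk;      // nm, kJ/mol/nm^2
  std::vector<int> tidx;           // bead type index, 0-based
  std::vector<double> c6, c12, vsh;  // nt*nt pair tables
  int nt;
  double cutoff2, cutoff;
  bool pbc;
  double box[3];
  std::unordered_set<long long> excl;
  // neighbour list
  std::vector<int> nli, nlj;
  std::vector<double> xref;
  double skin;

  bool excluded(int i, int j) const {
    long long a = i < j ? i : j, b = i < j ? j : i;
    return excl.count(a * (long long)n + b) > 0;
  }
  void dvec(int i, int j, double* d) const {
    for (int c = 0; c < 3; ++c) {
      d[c] = x[3 * j + c] - x[3 * i + c];
      if (pbc) d[c] -= box[c] * std::round(d[c] / box[c]);
    }
  }
  void buildList() {
    nli.clear(); nlj.clear();
    double rl2 = (cutoff + skin) * (cutoff + skin);
    double d[3];
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (excluded(i, j)) continue;
        dvec(i, j, d);
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (r2 < rl2) { nli.push_back(i); nlj.push_back(j); }
      }
    xref = x;
  }
  bool listStale() const {
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double d2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        double dd = x[3 * i + c] - xref[3 * i + c];
        d2 += dd * dd;
      }
      if (d2 > lim2) return true;
    }
    return false;
  }
};

// bond + LJ energy and forces; uses the neighbour list if use_list,
// otherwise loops over all non-excluded pairs.  mode: 0 = both terms,
// 1 = bonds only, 2 = LJ only (for the RESPA split in the integrator).
static double forces(System& S, std::vector<double>& f, bool use_list,
                     double* ebond_out = nullptr, double* elj_out = nullptr,
                     int mode = 0) {
  std::fill(f.begin(), f.end(), 0.0);
  double ebond = 0.0, elj = 0.0, d[3];
  if (mode != 2)
  for (size_t b = 0; b < S.bi.size(); ++b) {
    int i = S.bi[b], j = S.bj[b];
    S.dvec(i, j, d);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double dr = r - S.r0[b];
    ebond += 0.5 * S.bk[b] * dr * dr;
    double fac = -S.bk[b] * dr / r;  // force on j along d
    for (int c = 0; c < 3; ++c) {
      f[3 * j + c] += fac * d[c];
      f[3 * i + c] -= fac * d[c];
    }
  }
  auto ljpair = [&](int i, int j) {
    S.dvec(i, j, d);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= S.cutoff2) return;
    int t = S.tidx[i] * S.nt + S.tidx[j];
    double ir2 = 1.0 / r2, ir6 = ir2 * ir2 * ir2;
    elj += S.c12[t] * ir6 * ir6 - S.c6[t] * ir6 - S.vsh[t];
    double fac = (12.0 * S.c12[t] * ir6 * ir6 - 6.0 * S.c6[t] * ir6) * ir2;
    for (int c = 0; c < 3; ++c) {  // repulsive: force on j along +d
      f[3 * j + c] += fac * d[c];
      f[3 * i + c] -= fac * d[c];
    }
  };
  if (mode != 1) {
    if (use_list) {
      for (size_t p = 0; p < S.nli.size(); ++p) ljpair(S.nli[p], S.nlj[p]);
    } else {
      for (int i = 0; i < S.n; ++i)
        for (int j = i + 1; j < S.n; ++j)
          if (!S.excluded(i, j)) ljpair(i, j);
    }
  }
  if (ebond_out) *ebond_out = ebond;
  if (elj_out) *elj_out = elj;
  return ebond + elj;
}

static System makeSystem(NumericMatrix pos, IntegerVector bi, IntegerVector bj,
                         NumericVector r0, NumericVector bk,
                         IntegerVector tidx, NumericMatrix sigma,
                         NumericMatrix epsilon, IntegerVector ei,
                         IntegerVector ej, double cutoff, bool shift,
                         bool pbc, NumericVector box, double skin) {
  System S;
  S.n = pos.nrow();
  S.x.resize(3 * S.n);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) S.x[3 * i + c] = pos(i, c);
  S.bi.assign(bi.begin(), bi.end());
  S.bj.assign(bj.begin(), bj.end());
  S.r0.assign(r0.begin(), r0.end());
  S.bk.assign(bk.begin(), bk.end());
  S.tidx.assign(tidx.begin(), tidx.end());
  S.nt = sigma.nrow();
  S.c6.resize(S.nt * S.nt); S.c12.resize(S.nt * S.nt);
  S.vsh.resize(S.nt * S.nt);
  S.cutoff = cutoff;
  S.cutoff2 = cutoff * cutoff;
  for (int a = 0; a < S.nt; ++a)
    for (int b = 0; b < S.nt; ++b) {
      double sg = sigma(a, b), ep = epsilon(a, b);
      double s6 = sg * sg * sg * sg * sg * sg;
      double cc6 = 4.0 * ep * s6, cc12 = 4.0 * ep * s6 * s6;
      int t = a * S.nt + b;
      S.c6[t] = cc6; S.c12[t] = cc12;
      if (shift && std::isfinite(cutoff)) {
        double icr6 = 1.0 / (S.cutoff2 * S.cutoff2 * S.cutoff2);
        S.vsh[t] = cc12 * icr6 * icr6 - cc6 * icr6;
      } else S.vsh[t] = 0.0;
    }
  S.pbc = pbc;
  for (int c = 0; c < 3; ++c) S.box[c] = box[c];
  for (int k = 0; k < ei.size(); ++k) {
    int a = ei[k], b = ej[k];
    if (a > b) std::swap(a, b);
    S.excl.insert((long long)a * S.n + b);
  }
  S.skin = skin;
  return S;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, IntegerVector bi, IntegerVector bj,
                       NumericVector r0, NumericVector bk, IntegerVector tidx,
                       NumericMatrix sigma, NumericMatrix epsilon,
                       IntegerVector ei, IntegerVector ej, double cutoff,
                       bool shift, bool pbc, NumericVector box) {
  System S = makeSystem(pos, bi, bj, r0, bk, tidx, sigma, epsilon, ei, ej,
                        cutoff, shift, pbc, box, 0.0);
  std::vector<double> f(3 * S.n);
  double eb, el;
  double e = forces(S, f, false, &eb, &el);
  NumericMatrix fm(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) fm(i, c) = f[3 * i + c];
  return List::create(_["energy"] = e, _["bond"] = eb, _["lj"] = el,
                      _["forces"] = fm);
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, IntegerVector bi, IntegerVector bj,
                  NumericVector r0, NumericVector bk, IntegerVector tidx,
                  NumericMatrix sigma, NumericMatrix epsilon,
                  IntegerVector ei, IntegerVector ej, double cutoff,
                  bool shift, bool pbc, NumericVector box, int max_steps,
                  double ftol, double step0) {
  System S = makeSystem(pos, bi, bj, r0, bk, tidx, sigma, epsilon, ei, ej,
                        cutoff, shift, pbc, box, 0.0);
  std::vector<double> f(3 * S.n), xtrial(3 * S.n), ftrial(3 * S.n);
  double e = forces(S, f, false);
  if (!std::isfinite(e)) stop("numerical failure: non-finite initial energy");
  double h = step0;  // nm, displacement of the largest force component
  int it = 0;
  double fmax = 0.0;
  for (it = 0; it < max_steps; ++it) {
    fmax = 0.0;
    for (double v : f) fmax = std::max(fmax, std::fabs(v));
    if (fmax < ftol) break;
    for (int i = 0; i < 3 * S.n; ++i) xtrial[i] = S.x[i] + h * f[i] / fmax;
    std::swap(S.x, xtrial);
    double etrial = forces(S, ftrial, false);
    if (std::isfinite(etrial) && etrial < e) {
      e = etrial;
      std::swap(f, ftrial);
      h = std::min(h * 1.2, 0.2);
    } else {
      std::swap(S.x, xtrial);  // reject
      h *= 0.5;
      if (h < 1e-12) break;
    }
  }
  NumericMatrix out(S.n, 3);
  for (int i = 0; i < S.n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = S.x[3 * i + c];
  return List::create(_["pos"] = out, _["energy"] = e, _["fmax"] = fmax,
                      _["steps"] = it, _["converged"] = fmax < ftol);
}

static double kinetic(const std::vector<double>& v,
                      const std::vector<double>& m) {
  double k = 0.0;
  for (size_t i = 0; i < m.size(); ++i)
    for (int c = 0; c < 3; ++c)
      k += 0.5 * m[i] * v[3 * i + c] * v[3 * i + c];
  return k;
}

static void removeCom(std::vector<double>& v, const std::vector<double>& m) {
  double p[3] = {0, 0, 0}, M = 0.0;
  for (size_t i = 0; i < m.size(); ++i) {
    M += m[i];
    for (int c = 0; c < 3; ++c) p[c] += m[i] * v[3 * i + c];
  }
  for (size_t i = 0; i < m.size(); ++i)
    for (int c = 0; c < 3; ++c) v[3 * i + c] -= p[c] / M;
}

// Bussi stochastic velocity rescale factor alpha^2
static double bussiAlpha2(double kin, double kbar, int ndf, double c) {
  // c = exp(-dt/tau); kbar = target mean kinetic energy
  double r1 = norm_rand();
  // sum of (ndf-1) squared standard normals ~ chi^2 -> gamma draw
  double sumr2 = (ndf > 1) ? 2.0 * R::rgamma(0.5 * (ndf - 1), 1.0) : 0.0;
  double ratio = kbar / (ndf * kin);
  double a2 = c + (1.0 - c) * ratio * (r1 * r1 + sumr2) +
              2.0 * std::sqrt(c * (1.0 - c) * ratio) * r1;
  return a2;
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericVector mass, IntegerVector bi,
                IntegerVector bj, NumericVector r0, NumericVector bk,
                IntegerVector tidx, NumericMatrix sigma,
                NumericMatrix epsilon, IntegerVector ei, IntegerVector ej,
                double cutoff, bool shift, bool pbc, NumericVector box,
                double dt, double temperature, int thermostat, double gamma,
                double tau_t, int n_steps, int report_every, double skin,
                int n_inner) {
  System S = makeSystem(pos, bi, bj, r0, bk, tidx, sigma, epsilon, ei, ej,
                        cutoff, shift, pbc, box, skin);
  int n = S.n;
  std::vector<double> m(mass.begin(), mass.end());
  std::vector<double> v(3 * n, 0.0), f(3 * n);
  int ndf = 3 * n - 3;
  if (ndf < 1) ndf = 3 * n;

  RNGScope rngScope;
  if (temperature > 0) {
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(KB * temperature / m[i]);
      for (int c = 0; c < 3; ++c) v[3 * i + c] = sd * norm_rand();
    }
    removeCom(v, m);
    // rescale to the target temperature exactly after COM removal
    double k0 = kinetic(v, m);
    if (k0 > 0) {
      double lambda = std::sqrt(0.5 * ndf * KB * temperature / k0);
      for (double& vv : v) vv *= lambda;
    }
  }

  S.buildList();
  // RESPA split: the soft LJ forces act as impulses at the outer timestep
  // while the stiff elastic-network bonds are sub-integrated with
  // velocity Verlet at dt/n_inner, keeping the fast ribbon modes
  // accurately integrated at the production outer timestep.
  if (n_inner < 1) n_inner = 1;
  std::vector<double> fB(3 * n), fLJ(3 * n);
  double ebond = 0.0, elj = 0.0;
  forces(S, fB, true, &ebond, nullptr, 1);
  forces(S, fLJ, true, nullptr, &elj, 2);
  double epot = ebond + elj;
  if (!std::isfinite(epot)) stop("numerical failure: non-finite initial energy");

  int n_rep = n_steps / report_every;
  NumericVector frames(Dimension(n, 3, n_rep));
  NumericVector times(n_rep), v_epot(n_rep), v_ekin(n_rep), v_temp(n_rep);

  double c1 = (thermostat == 1) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (thermostat == 1) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  double cvr = (thermostat == 2) ? std::exp(-dt / tau_t) : 1.0;
  double kbar = 0.5 * ndf * KB * temperature;
  int rep = 0;
  // For Langevin the kinetic energy is measured at the mid-step (post-OU)
  // velocities: the on-step velocities of a BAOAB step systematically
  // under-read the kinetic temperature of stiff modes at finite timestep,
  // while the mid-step velocities are unbiased.
  double ekin_mid = 0.0;

  // n_in velocity-Verlet sub-steps of the bond-only system spanning `span`
  auto bondCycle = [&](double span, int n_in) {
    double delta = span / n_in;
    for (int s = 0; s < n_in; ++s) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          v[3 * i + c] += 0.5 * delta * fB[3 * i + c] / m[i];
      for (int i = 0; i < 3 * n; ++i) S.x[i] += delta * v[i];
      forces(S, fB, true, &ebond, nullptr, 1);
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          v[3 * i + c] += 0.5 * delta * fB[3 * i + c] / m[i];
    }
  };
  int m_in = (n_inner + 1) / 2;  // sub-steps per half-step block

  for (int step = 1; step <= n_steps; ++step) {
    // outer half kick (LJ impulse)
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        v[3 * i + c] += 0.5 * dt * fLJ[3 * i + c] / m[i];
    if (thermostat == 1) {
      // BAOAB with the A blocks carrying the sub-integrated bond dynamics
      bondCycle(0.5 * dt, m_in);
      if (temperature > 0 || gamma > 0) {
        for (int i = 0; i < n; ++i) {
          double sd = std::sqrt(KB * temperature / m[i]);
          for (int c = 0; c < 3; ++c)
            v[3 * i + c] = c1 * v[3 * i + c] + c2 * sd * norm_rand();
        }
        removeCom(v, m);
      }
      if (step % report_every == 0) ekin_mid = kinetic(v, m);
      bondCycle(0.5 * dt, m_in);
    } else {
      bondCycle(dt, n_inner);
    }
    if (S.listStale()) S.buildList();
    forces(S, fLJ, true, nullptr, &elj, 2);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        v[3 * i + c] += 0.5 * dt * fLJ[3 * i + c] / m[i];
    if (thermostat == 2 && temperature > 0) {
      double kin = kinetic(v, m);
      if (kin > 0) {
        double a2 = bussiAlpha2(kin, kbar, ndf, cvr);
        double a = std::sqrt(a2 < 0 ? 0 : a2);
        for (double& vv : v) vv *= a;
      }
    }
    epot = ebond + elj;
    if (!std::isfinite(epot) || epot > 1e12)
      stop("numerical failure: energy blow-up at step %d (timestep too "
           "large or overlapping beads)", step);
    if (step % report_every == 0) {
      double ekin = (thermostat == 1) ? ekin_mid : kinetic(v, m);
      times[rep] = step * dt;
      v_epot[rep] = epot;
      v_ekin[rep] = ekin;
      v_temp[rep] = 2.0 * ekin / (ndf * KB);
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          frames[rep * 3 * n + c * n + i] = S.x[3 * i + c];
      ++rep;
    }
  }
  NumericMatrix vout(n, 3), xout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      vout(i, c) = v[3 * i + c];
      xout(i, c) = S.x[3 * i + c];
    }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["epot"] = v_epot, _["ekin"] = v_ekin,
                      _["temperature"] = v_temp, _["final_pos"] = xout,
                      _["final_vel"] = vout);
}
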