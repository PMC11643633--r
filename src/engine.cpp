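// Compiled RK4 core for the mechanosensitive active gel model.
//
// Mirrors the R reference implementation (R/dynamics.R) with the "fd"
// backend: 2nd-order centered differences in flux form (exact discrete actin
// mass conservation), 5-point Laplacian, and an FFT Poisson solve using the
// FD Laplacian eigenvalues so that v = (Dy psi, -Dx psi) has exactly zero
// discrete divergence. Stiffness sensing, the myosin diffusivity field and
// the global polarity cue n_polar are frozen over each step's four RK4
// substages, exactly as in the R reference.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct Params {
  double a, k, alpha, kappa, c0;            // energy
  double eta, rho, gamma, xi, zeta;         // flow
  double D0, zeta_thr, Em, E0;              // mechanosensing
  double M, w, GammaP, Gammam, alpham, m0;  // transport / reaction
  double eps_n, dt, dx, dy;
  bool fickian;
};

class Engine {
public:
  Engine(const mat& E_, const Params& p_, bool freeze_flow_)
    : p(p_), E(E_), n1((int)E_.n_rows), n2((int)E_.n_cols),
      freeze_flow(freeze_flow_) {
    ip.set_size(n1); im.set_size(n1); jp.set_size(n2); jm.set_size(n2);
    for (int i = 0; i < n1; i++) { ip[i] = (i + 1) % n1; im[i] = (i + n1 - 1) % n1; }
    for (int j = 0; j < n2; j++) { jp[j] = (j + 1) % n2; jm[j] = (j + n2 - 1) % n2; }
    lam.set_size(n1, n2);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++)
        lam(i, j) = (2.0 * std::cos(2.0 * M_PI * i / n1) - 2.0) / (p.dx * p.dx)
                  + (2.0 * std::cos(2.0 * M_PI * j / n2) - 2.0) / (p.dy * p.dy);
    cosX.set_size(n1); sinX.set_size(n1); cosY.set_size(n2); sinY.set_size(n2);
    for (int i = 0; i < n1; i++) {
      double a0 = 2.0 * M_PI * i / n1; cosX[i] = std::cos(a0); sinX[i] = std::sin(a0);
    }
    for (int j = 0; j < n2; j++) {
      double a0 = 2.0 * M_PI * j / n2; cosY[j] = std::cos(a0); sinY[j] = std::sin(a0);
    }
    Lx = n1 * p.dx; Ly = n2 * p.dy;
  }

  // ---- FD operators ----------------------------------------------------
  void d_x(const mat& A, mat& B) const {
    const double f = 1.0 / (2.0 * p.dx);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++)
        B(i, j) = (A(ip[i], j) - A(im[i], j)) * f;
  }
  void d_y(const mat& A, mat& B) const {
    const double f = 1.0 / (2.0 * p.dy);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++)
        B(i, j) = (A(i, jp[j]) - A(i, jm[j])) * f;
  }
  void lap(const mat& A, mat& B) const {
    const double fx = 1.0 / (p.dx * p.dx), fy = 1.0 / (p.dy * p.dy);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++)
        B(i, j) = (A(ip[i], j) + A(im[i], j) - 2.0 * A(i, j)) * fx
                + (A(i, jp[j]) + A(i, jm[j]) - 2.0 * A(i, j)) * fy;
  }
  // -div(flux) accumulated into B: B -= Dx(fx) + Dy(fy)
  void minus_div(const mat& fx, const mat& fy, mat& B) const {
    const double gx = 1.0 / (2.0 * p.dx), gy = 1.0 / (2.0 * p.dy);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++)
        B(i, j) -= (fx(ip[i], j) - fx(im[i], j)) * gx
                 + (fy(i, jp[j]) - fy(i, jm[j])) * gy;
  }

  // ---- flow solve: psi from omega, v from psi --------------------------
  void solve_flow(const mat& omega, mat& psi, mat& vx, mat& vy) {
    cx_mat What = fft2(conv_to<cx_mat>::from(omega));
    What(0, 0) = 0.0; // zero-mean gauge
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++)
        if (i != 0 || j != 0) What(i, j) /= -lam(i, j); // lap psi = -omega
    psi = real(ifft2(What));
    d_y(psi, vx);
    d_x(psi, vy); vy *= -1.0;
  }

  // ---- circular (torus) centroid of a non-negative weight --------------
  bool centroid(const mat& w, double& cx, double& cy) const {
    double sx = 0, cxs = 0, sy = 0, cys = 0, tot = 0;
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double wv = w(i, j);
        if (wv > 0) { sx += wv * sinX[i]; cxs += wv * cosX[i];
                      sy += wv * sinY[j]; cys += wv * cosY[j]; tot += wv; }
      }
    if (!(tot > 0)) return false;
    cx = wrap0(std::atan2(sx, cxs) * Lx / (2.0 * M_PI), Lx);
    cy = wrap0(std::atan2(sy, cys) * Ly / (2.0 * M_PI), Ly);
    return true;
  }

  // x reduced into [0, L)
  static double wrap0(double x, double L) {
    double r = x - L * std::floor(x / L);
    return r >= L ? r - L : r;
  }

  static double torus_diff(double a, double b, double L) {
    double d = wrap0(a - b, L);
    return d > L / 2 ? d - L : d;
  }

  // ---- per-step frozen context: sensing, Dm, n_polar -------------------
  void step_context(const mat& c, const mat& m) {
    // cell support and sensed stiffness
    double Emin = datum::inf, Emax = -datum::inf, Esum = 0;
    int nmask = 0;
    mask.set_size(n1, n2);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        bool in = c(i, j) >= p.c0 / 2;
        mask(i, j) = in;
        if (in) {
          double e = E(i, j);
          if (e < Emin) Emin = e;
          if (e > Emax) Emax = e;
          Esum += e; nmask++;
        }
      }
    if (nmask == 0) Rcpp::stop("simulation failure: cell support is empty");
    double Eaver = Esum / nmask;
    sense_Emin = Emin; sense_Emax = Emax; sense_Eaver = Eaver;
    // Dm field
    Dm.set_size(n1, n2);
    if (Emax <= Emin) {
      for (int j = 0; j < n2; j++)
        for (int i = 0; i < n1; i++)
          Dm(i, j) = mask(i, j) ? 0.0 : p.D0;
    } else {
      double pref = p.zeta * p.D0 / p.zeta_thr;
      double gate = 1.0 - 1.0 / (1.0 + std::exp((p.Em - Eaver) / p.E0));
      for (int j = 0; j < n2; j++)
        for (int i = 0; i < n1; i++) {
          if (!mask(i, j)) { Dm(i, j) = p.D0; continue; }
          double q = (E(i, j) - Emin) / (Emax - Emin);
          double v = pref * q * q * gate;
          Dm(i, j) = v > 0 ? v : 0.0;
        }
    }
    // n_polar: from myosin centre (on support) to the cell centroid
    wtmp = c % conv_to<mat>::from(mask);
    double ccx, ccy, cmx, cmy;
    bool okc = centroid(wtmp, ccx, ccy);
    wtmp = m % conv_to<mat>::from(mask);
    bool okm = centroid(wtmp, cmx, cmy);
    np_null = true; np_len = 0; mpol = 0; qx = qy = 0;
    if (okc && okm) {
      double ox = torus_diff(ccx, cmx, Lx), oy = torus_diff(ccy, cmy, Ly);
      np_len = std::sqrt(ox * ox + oy * oy);
      mpol = -oy; // signed myosin offset along up-gradient (+y) axis
      if (np_len >= p.eps_n) {
        np_null = false;
        double nx = ox / np_len, ny = oy / np_len;
        qx = -ny; qy = nx; // q = R_{pi/2} n_polar (counter-clockwise)
      }
    }
    cell_cx = ccx; cell_cy = ccy;
  }

  // ---- combined RHS ----------------------------------------------------
  void rhs(const mat& c, const mat& m, const mat& Px, const mat& Py,
           const mat& omega,
           mat& dc, mat& dm, mat& dPx, mat& dPy, mat& dW) {
    // flow
    if (freeze_flow) { vx.zeros(n1, n2); vy.zeros(n1, n2); }
    else solve_flow(omega, psi, vx, vy);

    // common derivatives
    lap(c, lapc); d_x(c, gcx); d_y(c, gcy);
    lap(Px, lapPx); lap(Py, lapPy);
    d_x(Px, gPxx); d_y(Px, gPxy); d_x(Py, gPyx); d_y(Py, gPyy);

    // chemical potential and molecular field
    const double bulk = 8.0 * p.a / std::pow(p.c0, 4);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double cv = c(i, j);
        double P2 = Px(i, j) * Px(i, j) + Py(i, j) * Py(i, j);
        mu(i, j) = bulk * cv * (cv - p.c0) * (2.0 * cv - p.c0)
                 - p.k * lapc(i, j) - (p.alpha / p.c0) * P2;
        double pref = -p.alpha * (2.0 * cv - p.c0) / p.c0 + p.alpha * P2;
        hx(i, j) = pref * Px(i, j) - p.kappa * lapPx(i, j);
        hy(i, j) = pref * Py(i, j) - p.kappa * lapPy(i, j);
      }

    // actin: dc = -div(c (v + w P)) + M lap(mu)
    lap(mu, t1);
    dc = p.M * t1;
    t1 = c % (vx + p.w * Px);
    t2 = c % (vy + p.w * Py);
    minus_div(t1, t2, dc);

    // myosin: dm = -div(m (v - w P)) + diffusion - reaction
    lap(m, t3);
    if (p.fickian) {
      d_x(m, t1); d_y(m, t2);
      t1 %= Dm; t2 %= Dm;
      // div(Dm grad m)
      d_x(t1, t3); d_y(t2, t4); t3 += t4;
    } else {
      t3 %= Dm;
    }
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double d = 2.0 * c(i, j) - p.c0;
        double sgn = d > 0 ? 1.0 : (d < 0 ? -1.0 : 0.0);
        double mv = m(i, j);
        dm(i, j) = t3(i, j) - (p.alpham / p.Gammam) *
                   (-sgn * mv + mv * mv * mv / (p.m0 * p.m0));
      }
    t1 = m % (vx - p.w * Px);
    t2 = m % (vy - p.w * Py);
    minus_div(t1, t2, dm);

    // polarity
    d_x(vx, dvxx); d_x(vy, dvxy); d_y(vx, dvyx); d_y(vy, dvyy);
    const bool torque = !np_null && p.zeta != 0.0;
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double ux = vx(i, j) + p.w * Px(i, j);
        double uy = vy(i, j) + p.w * Py(i, j);
        double Oxy = 0.5 * (dvxy(i, j) - dvyx(i, j));
        double Vxy = 0.5 * (dvxy(i, j) + dvyx(i, j));
        double px = Px(i, j), py = Py(i, j);
        double ax = -(ux * gPxx(i, j) + uy * gPxy(i, j))
                    - Oxy * py + p.xi * (dvxx(i, j) * px + Vxy * py)
                    - hx(i, j) / p.GammaP;
        double ay = -(ux * gPyx(i, j) + uy * gPyy(i, j))
                    + Oxy * px + p.xi * (Vxy * px + dvyy(i, j) * py)
                    - hy(i, j) / p.GammaP;
        if (torque) {
          double Pq = px * qx + py * qy;
          ax -= p.zeta * Pq * (-py); // R P = (-Py, Px)
          ay -= p.zeta * Pq * (px);
        }
        dPx(i, j) = ax; dPy(i, j) = ay;
      }

    // vorticity
    if (freeze_flow) { dW.zeros(n1, n2); return; }
    // stresses: sigma_ij = -1/2(P_i h_j - h_i P_j) + xi/2 (P_i h_j + h_i P_j)
    //           - kappa sum_k d_i P_k d_j P_k  (elastic)
    //           + (f - c mu) delta_ij - k d_i c d_j c  (interfacial)
    //           + zeta c P_i P_j  (active)
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double cv = c(i, j), px = Px(i, j), py = Py(i, j);
        double hxv = hx(i, j), hyv = hy(i, j);
        double P2 = px * px + py * py;
        double f = 4.0 * p.a / std::pow(p.c0, 4) * cv * cv * (cv - p.c0) * (cv - p.c0)
                 + 0.5 * p.k * (gcx(i, j) * gcx(i, j) + gcy(i, j) * gcy(i, j))
                 - 0.5 * p.alpha * (2.0 * cv - p.c0) / p.c0 * P2
                 + 0.25 * p.alpha * P2 * P2
                 + 0.5 * p.kappa * (gPxx(i, j) * gPxx(i, j) + gPxy(i, j) * gPxy(i, j)
                                  + gPyx(i, j) * gPyx(i, j) + gPyy(i, j) * gPyy(i, j));
        double iso = f - cv * mu(i, j);
        double el_xx = p.xi * px * hxv
                     - p.kappa * (gPxx(i, j) * gPxx(i, j) + gPyx(i, j) * gPyx(i, j));
        double el_yy = p.xi * py * hyv
                     - p.kappa * (gPxy(i, j) * gPxy(i, j) + gPyy(i, j) * gPyy(i, j));
        double sym = 0.5 * p.xi * (px * hyv + hxv * py);
        double asym = -0.5 * (px * hyv - hxv * py);
        double el_xy = asym + sym
                     - p.kappa * (gPxx(i, j) * gPxy(i, j) + gPyx(i, j) * gPyy(i, j));
        double el_yx = -asym + sym
                     - p.kappa * (gPxy(i, j) * gPxx(i, j) + gPyy(i, j) * gPyx(i, j));
        sxx(i, j) = el_xx + iso - p.k * gcx(i, j) * gcx(i, j)
                  + p.zeta * cv * px * px;
        sxy(i, j) = el_xy - p.k * gcx(i, j) * gcy(i, j)
                  + p.zeta * cv * px * py;
        syx(i, j) = el_yx - p.k * gcy(i, j) * gcx(i, j)
                  + p.zeta * cv * py * px;
        syy(i, j) = el_yy + iso - p.k * gcy(i, j) * gcy(i, j)
                  + p.zeta * cv * py * py;
      }
    // G = Dx(Fy) - Dy(Fx), F_i = d_j sigma_ij
    d_x(sxx, t1); d_y(sxy, t2); t1 += t2; // Fx
    d_x(syx, t3); d_y(syy, t4); t3 += t4; // Fy
    d_x(t3, t2); d_y(t1, t4);
    // dW = (-rho v.grad w + eta lap w - gamma w + G)/rho
    d_x(omega, gwx); d_y(omega, gwy); lap(omega, lapw);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double G = t2(i, j) - t4(i, j);
        dW(i, j) = (-p.rho * (vx(i, j) * gwx(i, j) + vy(i, j) * gwy(i, j))
                    + p.eta * lapw(i, j) - p.gamma * omega(i, j) + G) / p.rho;
      }
  }

  // discrete free energy of the fd dynamics: forward-difference gradient
  // terms, the exact Lyapunov functional of the 5-point Laplacian mu and h
  double energy(const mat& c, const mat& Px, const mat& Py) {
    double F = 0;
    const double fx = 1.0 / p.dx, fy = 1.0 / p.dy;
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double cv = c(i, j);
        double P2 = Px(i, j) * Px(i, j) + Py(i, j) * Py(i, j);
        double gcx_ = (c(ip[i], j) - cv) * fx, gcy_ = (c(i, jp[j]) - cv) * fy;
        double gpxx = (Px(ip[i], j) - Px(i, j)) * fx;
        double gpxy = (Px(i, jp[j]) - Px(i, j)) * fy;
        double gpyx = (Py(ip[i], j) - Py(i, j)) * fx;
        double gpyy = (Py(i, jp[j]) - Py(i, j)) * fy;
        F += 4.0 * p.a / std::pow(p.c0, 4) * cv * cv * (cv - p.c0) * (cv - p.c0)
           + 0.5 * p.k * (gcx_ * gcx_ + gcy_ * gcy_)
           - 0.5 * p.alpha * (2.0 * cv - p.c0) / p.c0 * P2
           + 0.25 * p.alpha * P2 * P2
           + 0.5 * p.kappa * (gpxx * gpxx + gpxy * gpxy + gpyx * gpyx + gpyy * gpyy);
      }
    return F * p.dx * p.dy;
  }

  double max_abs_div(const mat& vx_, const mat& vy_) const {
    double mx = 0;
    const double gx = 1.0 / (2.0 * p.dx), gy = 1.0 / (2.0 * p.dy);
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++) {
        double d = (vx_(ip[i], j) - vx_(im[i], j)) * gx
                 + (vy_(i, jp[j]) - vy_(i, jm[j])) * gy;
        if (std::abs(d) > mx) mx = std::abs(d);
      }
    return mx;
  }

  Params p;
  mat E;
  int n1, n2;
  bool freeze_flow;
  double Lx, Ly;
  uvec ip, im, jp, jm;
  mat lam;
  vec cosX, sinX, cosY, sinY;
  // context
  umat mask; mat Dm, wtmp;
  double sense_Emin = 0, sense_Emax = 0, sense_Eaver = 0;
  bool np_null = true;
  double np_len = 0, qx = 0, qy = 0, mpol = 0, cell_cx = 0, cell_cy = 0;
  // work arrays
  mat psi, vx, vy, mu, hx, hy;
  mat lapc, gcx, gcy, lapPx, lapPy, gPxx, gPxy, gPyx, gPyy;
  mat dvxx, dvxy, dvyx, dvyy, gwx, gwy, lapw;
  mat sxx, sxy, syx, syy, t1, t2, t3, t4;

  void alloc() {
    for (mat* mm : {&psi, &vx, &vy, &mu, &hx, &hy, &lapc, &gcx, &gcy, &lapPx,
                    &lapPy, &gPxx, &gPxy, &gPyx, &gPyy, &dvxx, &dvxy, &dvyx,
                    &dvyy, &gwx, &gwy, &lapw, &sxx, &sxy, &syx, &syy,
                    &t1, &t2, &t3, &t4})
      mm->set_size(n1, n2);
  }
};

Params params_from_list(const Rcpp::List& par) {
  Rcpp::List en = par["energy"], fl = par["flow"], me = par["mech"];
  Params p;
  p.a = en["a"]; p.k = en["k"]; p.alpha = en["alpha"];
  p.kappa = en["kappa"]; p.c0 = en["c0"];
  p.eta = fl["eta"]; p.rho = fl["rho"]; p.gamma = fl["gamma"];
  p.xi = fl["xi"]; p.zeta = fl["zeta"];
  p.D0 = me["D0"]; p.zeta_thr = me["zeta_thr"]; p.Em = me["Em"]; p.E0 = me["E0"];
  p.M = par["M"]; p.w = par["w"]; p.GammaP = par["Gamma_P"];
  p.Gammam = par["Gamma_m"]; p.alpham = par["alpha_m"]; p.m0 = par["m0"];
  p.eps_n = par["eps_n"]; p.dt = par["dt"];
  p.fickian = Rcpp::as<bool>(par["fickian"]);
  return p;
}

} // namespace

// [[Rcpp::export(name = ".dg_engine_run")]]
Rcpp::List dg_engine_run(arma::mat c, arma::mat m, arma::mat Px, arma::mat Py,
                         arma::mat omega, const arma::mat& E,
                         const Rcpp::List& par, const Rcpp::List& ctrl) {
  Params p = params_from_list(par);
  p.dx = ctrl["dx"]; p.dy = ctrl["dy"];
  const int n_steps = ctrl["n_steps"];
  const int record_every = ctrl["record_every"];
  const int snapshot_every = ctrl["snapshot_every"];
  const bool freeze_flow = Rcpp::as<bool>(ctrl["freeze_flow"]);
  const double dt = p.dt;

  Engine eng(E, p, freeze_flow);
  eng.alloc();
  const int n1 = eng.n1, n2 = eng.n2;

  mat dc1(n1, n2), dm1(n1, n2), dPx1(n1, n2), dPy1(n1, n2), dW1(n1, n2);
  mat dcA(n1, n2), dmA(n1, n2), dPxA(n1, n2), dPyA(n1, n2), dWA(n1, n2);
  mat c2, m2, Px2, Py2, W2;

  const int n_rec = n_steps / record_every + 1;
  vec rt(n_rec), rx(n_rec), ry(n_rec), rmass(n_rec), rdiv(n_rec),
      rmmax(n_rec), rmpol(n_rec), renergy(n_rec), rnplen(n_rec);
  int irec = 0;
  double ux = 0, uy = 0;      // unwrapped centroid
  double px0 = 0, py0 = 0;    // previous wrapped centroid
  long clamp_count = 0;

  std::vector<int> snap_steps;
  Rcpp::List snaps;

  auto record = [&](int step, double t) {
    eng.step_context(c, m); // also computes centroid and mpol
    if (step == 0) { ux = eng.cell_cx; uy = eng.cell_cy; }
    else {
      ux += Engine::torus_diff(eng.cell_cx, px0, eng.Lx);
      uy += Engine::torus_diff(eng.cell_cy, py0, eng.Ly);
    }
    px0 = eng.cell_cx; py0 = eng.cell_cy;
    rt(irec) = t; rx(irec) = ux; ry(irec) = uy;
    rmass(irec) = accu(c) * p.dx * p.dy;
    if (freeze_flow) rdiv(irec) = 0;
    else { eng.solve_flow(omega, eng.psi, eng.vx, eng.vy);
           rdiv(irec) = eng.max_abs_div(eng.vx, eng.vy); }
    rmmax(irec) = m.max();
    rmpol(irec) = eng.mpol;
    rnplen(irec) = eng.np_len;
    renergy(irec) = eng.energy(c, Px, Py);
    irec++;
  };

  record(0, 0.0);

  for (int step = 1; step <= n_steps; step++) {
    eng.step_context(c, m); // frozen over the four substages

    eng.rhs(c, m, Px, Py, omega, dc1, dm1, dPx1, dPy1, dW1);
    dcA = dc1; dmA = dm1; dPxA = dPx1; dPyA = dPy1; dWA = dW1;

    c2 = c + (dt / 2) * dc1;  m2 = m + (dt / 2) * dm1;
    Px2 = Px + (dt / 2) * dPx1; Py2 = Py + (dt / 2) * dPy1;
    W2 = omega + (dt / 2) * dW1;
    eng.rhs(c2, m2, Px2, Py2, W2, dc1, dm1, dPx1, dPy1, dW1);
    dcA += 2 * dc1; dmA += 2 * dm1; dPxA += 2 * dPx1; dPyA += 2 * dPy1; dWA += 2 * dW1;

    c2 = c + (dt / 2) * dc1;  m2 = m + (dt / 2) * dm1;
    Px2 = Px + (dt / 2) * dPx1; Py2 = Py + (dt / 2) * dPy1;
    W2 = omega + (dt / 2) * dW1;
    eng.rhs(c2, m2, Px2, Py2, W2, dc1, dm1, dPx1, dPy1, dW1);
    dcA += 2 * dc1; dmA += 2 * dm1; dPxA += 2 * dPx1; dPyA += 2 * dPy1; dWA += 2 * dW1;

    c2 = c + dt * dc1;  m2 = m + dt * dm1;
    Px2 = Px + dt * dPx1; Py2 = Py + dt * dPy1;
    W2 = omega + dt * dW1;
    eng.rhs(c2, m2, Px2, Py2, W2, dc1, dm1, dPx1, dPy1, dW1);
    dcA += dc1; dmA += dm1; dPxA += dPx1; dPyA += dPy1; dWA += dW1;

    c += (dt / 6) * dcA; m += (dt / 6) * dmA;
    Px += (dt / 6) * dPxA; Py += (dt / 6) * dPyA;
    omega += (dt / 6) * dWA;

    // clamp advection overshoot of the myosin density
    for (int j = 0; j < n2; j++)
      for (int i = 0; i < n1; i++)
        if (m(i, j) < 0) { m(i, j) = 0; clamp_count++; }

    if (!c.is_finite() || !m.is_finite() || !Px.is_finite() ||
        !Py.is_finite() || !omega.is_finite())
      Rcpp::stop("simulation failure: non-finite field values at t = %g",
                 step * dt);

    if (step % record_every == 0) record(step, step * dt);
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      eng.solve_flow(omega, eng.psi, eng.vx, eng.vy);
      snaps.push_back(Rcpp::List::create(
        Rcpp::Named("t") = step * dt, Rcpp::Named("c") = c,
        Rcpp::Named("m") = m, Rcpp::Named("Px") = Px, Rcpp::Named("Py") = Py,
        Rcpp::Named("psi") = eng.psi, Rcpp::Named("omega") = omega,
        Rcpp::Named("vx") = eng.vx, Rcpp::Named("vy") = eng.vy));
    }
  }

  mat psi_f(n1, n2, fill::zeros), vx_f(n1, n2, fill::zeros),
      vy_f(n1, n2, fill::zeros);
  if (!freeze_flow) eng.solve_flow(omega, psi_f, vx_f, vy_f);

  return Rcpp::List::create(
    Rcpp::Named("t") = rt, Rcpp::Named("x") = rx, Rcpp::Named("y") = ry,
    Rcpp::Named("mass") = rmass, Rcpp::Named("max_div") = rdiv,
    Rcpp::Named("m_max") = rmmax, Rcpp::Named("m_polarization") = rmpol,
    Rcpp::Named("energy") = renergy, Rcpp::Named("npolar_len") = rnplen,
    Rcpp::Named("m_clamped") = (double)clamp_count,
    Rcpp::Named("final") = Rcpp::List::create(
      Rcpp::Named("c") = c, Rcpp::Named("m") = m, Rcpp::Named("Px") = Px,
      Rcpp::Named("Py") = Py, Rcpp::Named("omega") = omega,
      Rcpp::Named("psi") = psi_f, Rcpp::Named("vx") = vx_f,
      Rcpp::Named("vy") = vy_f),
    Rcpp::Named("snapshots") = snaps);
}

// [[Rcpp::export(name = ".dg_engine_rhs")]]
Rcpp::List dg_engine_rhs(const arma::mat& c, const arma::mat& m,
                         const arma::mat& Px, const arma::mat& Py,
                         const arma::mat& omega, const arma::mat& E,
                         const Rcpp::List& par, const Rcpp::List& ctrl) {
  // single RHS evaluation with per-step context; for cross-checking against
  // the R reference implementation
  Params p = params_from_list(par);
  p.dx = ctrl["dx"]; p.dy = ctrl["dy"];
  const bool freeze_flow = Rcpp::as<bool>(ctrl["freeze_flow"]);
  Engine eng(E, p, freeze_flow);
  eng.alloc();
  int n1 = eng.n1, n2 = eng.n2;
  mat dc(n1, n2), dm(n1, n2), dPx(n1, n2), dPy(n1, n2), dW(n1, n2);
  eng.step_context(c, m);
  eng.rhs(c, m, Px, Py, omega, dc, dm, dPx, dPy, dW);
  return Rcpp::List::create(
    Rcpp::Named("c") = dc, Rcpp::Named("m") = dm, Rcpp::Named("Px") = dPx,
    Rcpp::Named("Py") = dPy, Rcpp::Named("omega") = dW,
    Rcpp::Named("npolar_len") = eng.np_len,
    Rcpp::Named("npolar_null") = eng.np_null);
}
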