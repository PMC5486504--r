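// Staggered-grid (MAC) finite-volume solver for unsteady incompressible
// Newtonian flow on a masked Cartesian grid, with SIMPLE pressure-velocity
// coupling. First-order upwind convection, central diffusion, implicit
// Euler in time. Boundary conditions: fixed flat velocity profile at the
// inlet column, zero gauge pressure with zero-gradient velocity at the
// outlet, no-slip on all solid faces (wall shear is recovered from the
// half-cell gradient next to masked cells).
//
// All quantities are SI and per unit depth (2-D).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny;
  std::vector<int> fluid;  // nx*ny, 0/1
  bool F(int i, int j) const {
    if (i < 0 || i >= nx || j < 0 || j >= ny) return false;
    return fluid[i + j * nx] != 0;
  }
};

// u-face types: 0 zero/wall, 1 fixed inlet, 2 interior, 3 outlet
// v-face types: 0 zero/wall, 2 interior

}  // namespace

// [[Rcpp::export]]
List simple_solve_cpp(LogicalMatrix fluid_in, double h, double rho, double mu,
                      NumericVector uin_series, IntegerVector inlet_rows,
                      int n_steps_per_cycle, int n_cycles, double dt,
                      double alpha_u, double alpha_p,
                      double tol_mass, double tol_u,
                      int max_outer, int n_sweeps,
                      double cg_rtol, int cg_maxit) {
  Grid g;
  g.nx = fluid_in.nrow();
  g.ny = fluid_in.ncol();
  const int nx = g.nx, ny = g.ny;
  g.fluid.assign(nx * ny, 0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      g.fluid[i + j * nx] = fluid_in(i, j) ? 1 : 0;

  const int nu = (nx + 1) * ny;   // u at vertical faces
  const int nv = nx * (ny + 1);   // v at horizontal faces
  const int np = nx * ny;
  auto IU = [nx](int iu, int j) { return iu + j * (nx + 1); };
  auto IV = [nx](int i, int jv) { return i + jv * nx; };
  auto IP = [nx](int i, int j) { return i + j * nx; };

  // face classification
  std::vector<int> utype(nu, 0), vtype(nv, 0);
  std::vector<int> is_inlet_row(ny, 0);
  for (int k = 0; k < inlet_rows.size(); ++k) is_inlet_row[inlet_rows[k]] = 1;
  for (int j = 0; j < ny; ++j) {
    for (int iu = 0; iu <= nx; ++iu) {
      if (iu == 0) {
        if (g.F(0, j) && is_inlet_row[j]) utype[IU(iu, j)] = 1;
      } else if (iu == nx) {
        if (g.F(nx - 1, j)) utype[IU(iu, j)] = 3;
      } else if (g.F(iu - 1, j) && g.F(iu, j)) {
        utype[IU(iu, j)] = 2;
      }
    }
  }
  for (int jv = 1; jv < ny; ++jv)
    for (int i = 0; i < nx; ++i)
      if (g.F(i, jv - 1) && g.F(i, jv)) vtype[IV(i, jv)] = 2;

  // fluid-cell compact indexing for the pressure correction
  std::vector<int> cidx(np, -1);
  std::vector<int> ci, cj;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (g.F(i, j)) {
        cidx[IP(i, j)] = (int)ci.size();
        ci.push_back(i);
        cj.push_back(j);
      }
  const int nc = (int)ci.size();

  // state
  std::vector<double> u(nu, 0.0), v(nv, 0.0), p(np, 0.0);
  std::vector<double> u_old(nu, 0.0), v_old(nv, 0.0);
  std::vector<double> u_it(nu, 0.0), v_it(nv, 0.0);  // start-of-outer copy

  // momentum coefficient arrays
  std::vector<double> uaP(nu), uaE(nu), uaW(nu), uaN(nu), uaS(nu), ub(nu),
      ud(nu, 0.0);
  std::vector<double> vaP(nv), vaE(nv), vaW(nv), vaN(nv), vaS(nv), vb(nv),
      vd(nv, 0.0);

  // pressure-correction arrays (compact cell indexing)
  std::vector<double> pdiag(nc), plinkE(nc), plinkN(nc), pb(nc), pc(nc);
  std::vector<int> pE(nc, -1), pN(nc, -1);
  for (int c = 0; c < nc; ++c) {
    int i = ci[c], j = cj[c];
    if (g.F(i + 1, j)) pE[c] = cidx[IP(i + 1, j)];
    if (g.F(i, j + 1)) pN[c] = cidx[IP(i, j + 1)];
  }
  // CG work arrays
  std::vector<double> cg_r(nc), cg_z(nc), cg_pv(nc), cg_Ap(nc);

  const double D = mu;          // diffusion conductance per unit depth
  const double aP0 = rho * h * h / dt;
  const int n_steps = n_steps_per_cycle * n_cycles;
  const int first_save = (n_cycles - 1) * n_steps_per_cycle;  // steps > this
  const int n_save = n_steps_per_cycle;

  NumericVector out_u(Dimension(nx + 1, ny, n_save));
  NumericVector out_v(Dimension(nx, ny + 1, n_save));
  NumericVector out_p(Dimension(nx, ny, n_save));
  NumericMatrix res_log(n_steps, 3);  // step, outer iters, final mass residual
  double cfl_max = 0.0;
  int failed_step = -1;
  std::vector<double> fail_hist;

  const int n_inlet = inlet_rows.size();

  for (int step = 1; step <= n_steps; ++step) {
    const double uin = uin_series[step - 1];
    u_old = u;
    v_old = v;
    for (int k = 0; k < n_inlet; ++k) u[IU(0, inlet_rows[k])] = uin;

    const double scale = std::max(rho * std::fabs(uin) * n_inlet * h, 1e-12);
    double res_mass = 0.0;
    int outer = 0;
    bool converged = false;
    std::vector<double> hist;

    for (outer = 1; outer <= max_outer; ++outer) {
      u_it = u;
      v_it = v;

      // ---- assemble u-momentum ----
      for (int j = 0; j < ny; ++j) {
        for (int iu = 1; iu <= nx; ++iu) {
          const int k = IU(iu, j);
          const int t = utype[k];
          if (t != 2 && t != 3) continue;
          double Fe, Fw, Fn, Fs;
          double aE, aW, aN, aS, wall = 0.0, b = 0.0;
          if (t == 2) {
            Fe = 0.5 * rho * h * (u[IU(iu, j)] + u[IU(iu + 1, j)]);
            Fw = 0.5 * rho * h * (u[IU(iu - 1, j)] + u[IU(iu, j)]);
            Fn = 0.5 * rho * h * (v[IV(iu - 1, j + 1)] + v[IV(iu, j + 1)]);
            Fs = 0.5 * rho * h * (v[IV(iu - 1, j)] + v[IV(iu, j)]);
            aE = D + std::max(-Fe, 0.0);
            aW = D + std::max(Fw, 0.0);
            // north neighbour u(iu, j+1): open if any adjacent cell is fluid
            if (g.F(iu - 1, j + 1) || g.F(iu, j + 1)) {
              aN = D + std::max(-Fn, 0.0);
            } else {  // solid above: wall at h/2
              aN = 0.0;
              wall += 2.0 * D;
            }
            if (g.F(iu - 1, j - 1) || g.F(iu, j - 1)) {
              aS = D + std::max(Fs, 0.0);
            } else {
              aS = 0.0;
              wall += 2.0 * D;
            }
            b = h * (p[IP(iu - 1, j)] - p[IP(iu, j)]);
          } else {  // outlet face, CV collapsed onto cell nx-1
            Fe = rho * h * u[IU(nx, j)];
            Fw = 0.5 * rho * h * (u[IU(nx - 1, j)] + u[IU(nx, j)]);
            Fn = rho * h * v[IV(nx - 1, j + 1)];
            Fs = rho * h * v[IV(nx - 1, j)];
            aE = 0.0;  // zero-gradient outflow
            aW = D + std::max(Fw, 0.0);
            if (g.F(nx - 1, j + 1)) {
              aN = D + std::max(-Fn, 0.0);
            } else {
              aN = 0.0;
              wall += 2.0 * D;
            }
            if (g.F(nx - 1, j - 1)) {
              aS = D + std::max(Fs, 0.0);
            } else {
              aS = 0.0;
              wall += 2.0 * D;
            }
            b = h * p[IP(nx - 1, j)];  // outlet gauge pressure = 0
          }
          const double dF = Fe - Fw + Fn - Fs;
          const double aP =
              aE + aW + aN + aS + wall + aP0 + std::max(dF, 0.0);
          b += aP0 * u_old[k];
          uaP[k] = aP; uaE[k] = aE; uaW[k] = aW; uaN[k] = aN; uaS[k] = aS;
          ub[k] = b;
          ud[k] = alpha_u * h / aP;
        }
      }

      // ---- assemble v-momentum ----
      for (int jv = 1; jv < ny; ++jv) {
        for (int i = 0; i < nx; ++i) {
          const int k = IV(i, jv);
          if (vtype[k] != 2) continue;
          const double Fe =
              0.5 * rho * h * (u[IU(i + 1, jv - 1)] + u[IU(i + 1, jv)]);
          const double Fw = 0.5 * rho * h * (u[IU(i, jv - 1)] + u[IU(i, jv)]);
          const double Fn = 0.5 * rho * h * (v[IV(i, jv)] + v[IV(i, jv + 1)]);
          const double Fs =
              0.5 * rho * h * (v[IV(i, jv - 1)] + v[IV(i, jv)]);
          double aE, aW, wall = 0.0;
          if (i + 1 >= nx) {
            aE = 0.0;  // outlet: zero-gradient tangential velocity
          } else if (g.F(i + 1, jv - 1) || g.F(i + 1, jv)) {
            aE = D + std::max(-Fe, 0.0);
          } else {
            aE = 0.0;
            wall += 2.0 * D;
          }
          if (i - 1 < 0) {
            aW = 0.0;  // inlet plane: flat profile, tangential v = 0 at x=0
            wall += 2.0 * D;
          } else if (g.F(i - 1, jv - 1) || g.F(i - 1, jv)) {
            aW = D + std::max(Fw, 0.0);
          } else {
            aW = 0.0;
            wall += 2.0 * D;
          }
          const double aN = D + std::max(-Fn, 0.0);
          const double aS = D + std::max(Fs, 0.0);
          const double dF = Fe - Fw + Fn - Fs;
          const double aP =
              aE + aW + aN + aS + wall + aP0 + std::max(dF, 0.0);
          const double b = h * (p[IP(i, jv - 1)] - p[IP(i, jv)]) +
                           aP0 * v_old[k];
          vaP[k] = aP; vaE[k] = aE; vaW[k] = aW; vaN[k] = aN; vaS[k] = aS;
          vb[k] = b;
          vd[k] = alpha_u * h / aP;
        }
      }

      // ---- under-relaxed Gauss-Seidel sweeps ----
      for (int sweep = 0; sweep < n_sweeps; ++sweep) {
        for (int j = 0; j < ny; ++j) {
          for (int iu = 1; iu <= nx; ++iu) {
            const int k = IU(iu, j);
            const int t = utype[k];
            if (t != 2 && t != 3) continue;
            double s = ub[k] + uaW[k] * u[IU(iu - 1, j)];
            if (iu < nx) s += uaE[k] * u[IU(iu + 1, j)];
            if (j + 1 < ny) s += uaN[k] * u[IU(iu, j + 1)];
            if (j - 1 >= 0) s += uaS[k] * u[IU(iu, j - 1)];
            u[k] = (1.0 - alpha_u) * u_it[k] + alpha_u * (s / uaP[k]);
          }
        }
        for (int jv = 1; jv < ny; ++jv) {
          for (int i = 0; i < nx; ++i) {
            const int k = IV(i, jv);
            if (vtype[k] != 2) continue;
            double s = vb[k];
            if (i + 1 < nx) s += vaE[k] * v[IV(i + 1, jv)];
            if (i - 1 >= 0) s += vaW[k] * v[IV(i - 1, jv)];
            s += vaN[k] * v[IV(i, jv + 1)];
            s += vaS[k] * v[IV(i, jv - 1)];
            v[k] = (1.0 - alpha_u) * v_it[k] + alpha_u * (s / vaP[k]);
          }
        }
      }

      // ---- mass imbalance and convergence check ----
      res_mass = 0.0;
      for (int c = 0; c < nc; ++c) {
        const int i = ci[c], j = cj[c];
        const double b = rho * h * (u[IU(i, j)] - u[IU(i + 1, j)] +
                                    v[IV(i, j)] - v[IV(i, j + 1)]);
        pb[c] = b;
        res_mass += std::fabs(b);
      }
      res_mass /= scale;
      hist.push_back(res_mass);

      double du_max = 0.0, uref = 1e-12;
      for (int k = 0; k < nu; ++k) {
        du_max = std::max(du_max, std::fabs(u[k] - u_it[k]));
        uref = std::max(uref, std::fabs(u[k]));
      }
      for (int k = 0; k < nv; ++k) {
        du_max = std::max(du_max, std::fabs(v[k] - v_it[k]));
        uref = std::max(uref, std::fabs(v[k]));
      }
      if (res_mass < tol_mass && du_max / uref < tol_u) {
        converged = true;
        break;
      }

      // ---- pressure-correction Poisson (SPD; Jacobi-preconditioned CG) ----
      for (int c = 0; c < nc; ++c) {
        const int i = ci[c], j = cj[c];
        double diag = 0.0, cE = 0.0, cN = 0.0;
        const int keast = IU(i + 1, j);
        if (utype[keast] == 2) {
          cE = rho * h * ud[keast];
          diag += cE;
        } else if (utype[keast] == 3) {
          diag += rho * h * ud[keast];  // p' = 0 beyond the outlet
        }
        const int kwest = IU(i, j);
        if (utype[kwest] == 2) diag += rho * h * ud[kwest];
        const int knorth = IV(i, j + 1);
        if (vtype[knorth] == 2) {
          cN = rho * h * vd[knorth];
          diag += cN;
        }
        const int ksouth = IV(i, j);
        if (vtype[ksouth] == 2) diag += rho * h * vd[ksouth];
        pdiag[c] = std::max(diag, 1e-300);
        plinkE[c] = cE;
        plinkN[c] = cN;
      }

      // CG solve A pc = pb, pc0 = 0
      std::fill(pc.begin(), pc.end(), 0.0);
      double bnorm = 0.0;
      for (int c = 0; c < nc; ++c) bnorm += pb[c] * pb[c];
      bnorm = std::sqrt(bnorm);
      if (bnorm > 0.0) {
        cg_r = pb;
        double rz = 0.0;
        for (int c = 0; c < nc; ++c) {
          cg_z[c] = cg_r[c] / pdiag[c];
          rz += cg_r[c] * cg_z[c];
        }
        cg_pv = cg_z;
        const double target = cg_rtol * bnorm;
        for (int it = 0; it < cg_maxit; ++it) {
          // Ap = A * pv (symmetric 5-point)
          for (int c = 0; c < nc; ++c) cg_Ap[c] = pdiag[c] * cg_pv[c];
          for (int c = 0; c < nc; ++c) {
            if (pE[c] >= 0 && plinkE[c] != 0.0) {
              cg_Ap[c] -= plinkE[c] * cg_pv[pE[c]];
              cg_Ap[pE[c]] -= plinkE[c] * cg_pv[c];
            }
            if (pN[c] >= 0 && plinkN[c] != 0.0) {
              cg_Ap[c] -= plinkN[c] * cg_pv[pN[c]];
              cg_Ap[pN[c]] -= plinkN[c] * cg_pv[c];
            }
          }
          double pAp = 0.0;
          for (int c = 0; c < nc; ++c) pAp += cg_pv[c] * cg_Ap[c];
          if (pAp <= 0.0) break;
          const double alpha = rz / pAp;
          double rnorm = 0.0;
          for (int c = 0; c < nc; ++c) {
            pc[c] += alpha * cg_pv[c];
            cg_r[c] -= alpha * cg_Ap[c];
            rnorm += cg_r[c] * cg_r[c];
          }
          if (std::sqrt(rnorm) <= target) break;
          double rz_new = 0.0;
          for (int c = 0; c < nc; ++c) {
            cg_z[c] = cg_r[c] / pdiag[c];
            rz_new += cg_r[c] * cg_z[c];
          }
          const double beta = rz_new / rz;
          rz = rz_new;
          for (int c = 0; c < nc; ++c) cg_pv[c] = cg_z[c] + beta * cg_pv[c];
        }
      }

      // ---- apply corrections ----
      for (int c = 0; c < nc; ++c) p[IP(ci[c], cj[c])] += alpha_p * pc[c];
      for (int j = 0; j < ny; ++j) {
        for (int iu = 1; iu <= nx; ++iu) {
          const int k = IU(iu, j);
          if (utype[k] == 2) {
            const double pw = pc[cidx[IP(iu - 1, j)]];
            const double pe = pc[cidx[IP(iu, j)]];
            u[k] += ud[k] * (pw - pe);
          } else if (utype[k] == 3) {
            u[k] += ud[k] * pc[cidx[IP(nx - 1, j)]];
          }
        }
      }
      for (int jv = 1; jv < ny; ++jv) {
        for (int i = 0; i < nx; ++i) {
          const int k = IV(i, jv);
          if (vtype[k] != 2) continue;
          const double ps = pc[cidx[IP(i, jv - 1)]];
          const double pn = pc[cidx[IP(i, jv)]];
          v[k] += vd[k] * (ps - pn);
        }
      }
    }  // outer

    res_log(step - 1, 0) = step;
    res_log(step - 1, 1) = std::min(outer, max_outer);
    res_log(step - 1, 2) = res_mass;

    if (!converged) {
      failed_step = step;
      fail_hist = hist;
      break;
    }

    double umax = 0.0;
    for (int k = 0; k < nu; ++k) umax = std::max(umax, std::fabs(u[k]));
    for (int k = 0; k < nv; ++k) umax = std::max(umax, std::fabs(v[k]));
    cfl_max = std::max(cfl_max, umax * dt / h);

    if (step > first_save) {
      const int slot = step - first_save - 1;
      std::copy(u.begin(), u.end(), out_u.begin() + (R_xlen_t)slot * nu);
      std::copy(v.begin(), v.end(), out_v.begin() + (R_xlen_t)slot * nv);
      std::copy(p.begin(), p.end(), out_p.begin() + (R_xlen_t)slot * np);
    }
  }  // time loop

  return List::create(
      _["u"] = out_u, _["v"] = out_v, _["p"] = out_p,
      _["residual_log"] = res_log, _["cfl_max"] = cfl_max,
      _["failed_step"] = failed_step,
      _["failure_residuals"] = NumericVector(fail_hist.begin(),
                                             fail_hist.end()));
}
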