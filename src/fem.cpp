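// Hexahedral finite-element core: Mooney-Rivlin ground matrix with
// logarithmic volumetric term, an additional soft-incompressibility
// quadratic bulk penalty, and embedded transversely isotropic muscle
// fibres.  Works in the consistent mm / tonne / s / MPa unit system; all
// parameters arrive already converted by the R glue.
//
// The residual (internal force) is exact; the tangent is assembled from a
// central finite difference of the first Piola stress per Gauss point.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct MatPars {
  double c10, c20, kappa, bulk;       // MPa
  double p1, p2, lam_star, lam_ofl;   // fibre law
  double sigma_max;                   // MPa
};

// trilinear shape-function gradients at a Gauss point (8 x 3, natural coords)
void shape_grad(double xi, double eta, double ze, arma::mat::fixed<8, 3> &dN) {
  const double s[8][3] = {{-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
                          {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}};
  for (int a = 0; a < 8; ++a) {
    const double sx = s[a][0], sy = s[a][1], sz = s[a][2];
    dN(a, 0) = 0.125 * sx * (1 + sy * eta) * (1 + sz * ze);
    dN(a, 1) = 0.125 * sy * (1 + sx * xi) * (1 + sz * ze);
    dN(a, 2) = 0.125 * sz * (1 + sx * xi) * (1 + sy * eta);
  }
}

// normalised passive fibre force (exponential, linear beyond lam_star)
double fib_passive(double lb, const MatPars &mp) {
  if (lb <= 1.0) return 0.0;
  if (lb < mp.lam_star) return mp.p1 * (std::exp(mp.p2 * (lb - 1.0)) - 1.0);
  const double f_star = mp.p1 * (std::exp(mp.p2 * (mp.lam_star - 1.0)) - 1.0);
  const double slope = mp.p1 * mp.p2 * std::exp(mp.p2 * (mp.lam_star - 1.0));
  return f_star + slope * (lb - mp.lam_star);
}

double fib_passive_int(double lb, const MatPars &mp) { // int_1^lb f_p
  if (lb <= 1.0) return 0.0;
  const double ls = mp.lam_star;
  auto seg = [&](double u) { // antiderivative of exponential branch
    return mp.p1 * (std::exp(mp.p2 * (u - 1.0)) / mp.p2 - u);
  };
  if (lb < ls) return seg(lb) - seg(1.0);
  const double base = seg(ls) - seg(1.0);
  const double f_star = mp.p1 * (std::exp(mp.p2 * (ls - 1.0)) - 1.0);
  const double slope = mp.p1 * mp.p2 * std::exp(mp.p2 * (ls - 1.0));
  const double d = lb - ls;
  return base + f_star * d + 0.5 * slope * d * d;
}

// normalised active force-length: parabola peaking at lb = 1, support [0.5, 1.5]
double fib_active(double lb) {
  const double v = 1.0 - 4.0 * (lb - 1.0) * (lb - 1.0);
  return v > 0.0 ? v : 0.0;
}

double fib_active_int(double lb, const MatPars &) { // int_1^lb f_a
  auto prim = [](double u) { // valid on [0.5, 1.5]
    const double d = u - 1.0;
    return d - (4.0 / 3.0) * d * d * d;
  };
  if (lb > 1.5) return prim(1.5);
  if (lb < 0.5) return prim(0.5);
  return prim(lb);
}

struct FibreAtGp {
  arma::vec3 a0;   // unit reference direction
  double act;      // activation in [0, 1]
};

// energy density and first Piola stress at one Gauss point; returns false on
// inverted configuration (det F <= 0)
bool point_stress(const arma::mat33 &F, const MatPars &mp,
                  const std::vector<FibreAtGp> &fibs, double &W,
                  arma::mat33 &P, bool want_P) {
  const double J = arma::det(F);
  if (!(J > 0.0)) return false;
  const double Jm23 = std::pow(J, -2.0 / 3.0);
  const double I1 = arma::accu(F % F);
  const double I1b = Jm23 * I1;
  const double lnJ = std::log(J);
  const double dev = mp.c10 + 2.0 * mp.c20 * (I1b - 3.0);
  W = mp.c10 * (I1b - 3.0) + mp.c20 * (I1b - 3.0) * (I1b - 3.0) +
      0.5 * mp.kappa * lnJ * lnJ + 0.5 * mp.bulk * (J - 1.0) * (J - 1.0);
  arma::mat33 FinvT;
  if (want_P || !fibs.empty()) {
    FinvT = arma::inv(F).t();
  }
  if (want_P) {
    P = dev * 2.0 * Jm23 * (F - (I1 / 3.0) * FinvT) +
        (mp.kappa * lnJ + mp.bulk * J * (J - 1.0)) * FinvT;
  }
  for (const FibreAtGp &fb : fibs) {
    const arma::vec3 Fa = F * fb.a0;
    const double lam = arma::norm(Fa);
    const double lb = lam / mp.lam_ofl;
    W += mp.sigma_max * mp.lam_ofl *
         (fib_passive_int(lb, mp) + fb.act * fib_active_int(lb, mp));
    if (want_P) {
      const double s = mp.sigma_max *
                       (fib_passive(lb, mp) + fb.act * fib_active(lb));
      if (s != 0.0 && lam > 1e-12) {
        P += (s / lam) * (Fa * fb.a0.t());
      }
    }
  }
  return true;
}

MatPars read_pars(const List &pars) {
  MatPars mp;
  mp.c10 = pars["c10"]; mp.c20 = pars["c20"]; mp.kappa = pars["kappa"];
  mp.bulk = pars["bulk"]; mp.p1 = pars["p1"]; mp.p2 = pars["p2"];
  mp.lam_star = pars["lam_star"]; mp.lam_ofl = pars["lam_ofl"];
  mp.sigma_max = pars["sigma_max"];
  return mp;
}

// build per-element fibre lists from flat vectors (elem ids 1-based)
std::vector<std::vector<FibreAtGp>> fibres_by_element(
    int ne, const IntegerVector &fib_elem, const NumericMatrix &fib_dir,
    const NumericVector &fib_act) {
  std::vector<std::vector<FibreAtGp>> out(ne);
  for (int k = 0; k < fib_elem.size(); ++k) {
    FibreAtGp fb;
    fb.a0 = {fib_dir(k, 0), fib_dir(k, 1), fib_dir(k, 2)};
    fb.act = fib_act[k];
    out[fib_elem[k] - 1].push_back(fb);
  }
  return out;
}

const double GP = 0.5773502691896258; // 1/sqrt(3)

} // namespace

// accumulate per-element stiffness values into the sparse @x slot layout
// (map is 1-based, length of vals; n is the number of stored entries)
// [[Rcpp::export]]
NumericVector fem_aggregate(const NumericVector &vals,
                            const IntegerVector &map, int n) {
  NumericVector out(n);
  for (int k = 0; k < vals.size(); ++k) out[map[k] - 1] += vals[k];
  return out;
}

// [[Rcpp::export]]
arma::vec fem_hex_volumes(const arma::mat &nodes, const arma::imat &elems) {
  const int ne = elems.n_rows;
  arma::vec vol(ne, arma::fill::zeros);
  arma::mat::fixed<8, 3> dN;
  for (int e = 0; e < ne; ++e) {
    arma::mat::fixed<8, 3> Xe;
    for (int a = 0; a < 8; ++a) Xe.row(a) = nodes.row(elems(e, a) - 1);
    for (int g = 0; g < 8; ++g) {
      const double xi = (g & 1) ? GP : -GP;
      const double eta = (g & 2) ? GP : -GP;
      const double ze = (g & 4) ? GP : -GP;
      shape_grad(xi, eta, ze, dN);
      arma::mat33 Jref = Xe.t() * dN;
      vol(e) += arma::det(Jref);
    }
  }
  return vol;
}

// [[Rcpp::export]]
arma::vec fem_lumped_mass(const arma::mat &nodes, const arma::imat &elems,
                          double density) {
  const int ne = elems.n_rows;
  arma::vec m(nodes.n_rows, arma::fill::zeros);
  arma::mat::fixed<8, 3> dN;
  for (int e = 0; e < ne; ++e) {
    arma::mat::fixed<8, 3> Xe;
    for (int a = 0; a < 8; ++a) Xe.row(a) = nodes.row(elems(e, a) - 1);
    double vol = 0.0;
    for (int g = 0; g < 8; ++g) {
      const double xi = (g & 1) ? GP : -GP;
      const double eta = (g & 2) ? GP : -GP;
      const double ze = (g & 4) ? GP : -GP;
      shape_grad(xi, eta, ze, dN);
      vol += arma::det(Xe.t() * dN);
    }
    const double share = density * vol / 8.0; // row-sum lumping
    for (int a = 0; a < 8; ++a) m(elems(e, a) - 1) += share;
  }
  return m;
}

// Assemble total strain energy, internal force and (optionally) the tangent
// stiffness values (per-element 24x24 blocks, column-major).  Returns the
// first inverted element (1-based) or 0.
// [[Rcpp::export]]
List fem_assemble(const arma::mat &nodes, const arma::imat &elems,
                  const arma::mat &x, const List &pars,
                  const IntegerVector &fib_elem, const NumericMatrix &fib_dir,
                  const NumericVector &fib_act, bool stiffness) {
  const MatPars mp = read_pars(pars);
  const int ne = elems.n_rows;
  const int nn = nodes.n_rows;
  auto fibs = fibres_by_element(ne, fib_elem, fib_dir, fib_act);

  double energy = 0.0;
  arma::mat force(nn, 3, arma::fill::zeros);
  arma::vec kvals;
  if (stiffness) kvals.zeros((size_t)ne * 576);
  double min_detF = arma::datum::inf, max_detF = -arma::datum::inf;
  int inverted = 0;

  arma::mat::fixed<8, 3> dN;
  const double hfd = 1e-6;

  for (int e = 0; e < ne && inverted == 0; ++e) {
    arma::mat::fixed<8, 3> Xe, xe;
    for (int a = 0; a < 8; ++a) {
      Xe.row(a) = nodes.row(elems(e, a) - 1);
      xe.row(a) = x.row(elems(e, a) - 1);
    }
    arma::mat::fixed<24, 24> Ke;
    if (stiffness) Ke.zeros();
    arma::mat::fixed<8, 3> fe;
    fe.zeros();

    for (int g = 0; g < 8; ++g) {
      const double xi = (g & 1) ? GP : -GP;
      const double eta = (g & 2) ? GP : -GP;
      const double ze = (g & 4) ? GP : -GP;
      shape_grad(xi, eta, ze, dN);
      const arma::mat33 Jref = Xe.t() * dN;      // reference Jacobian
      const double detJ0 = arma::det(Jref);
      const arma::mat dNdX = dN * arma::inv(Jref); // 8 x 3
      const arma::mat33 F = xe.t() * dNdX;

      double W;
      arma::mat33 P;
      if (!point_stress(F, mp, fibs[e], W, P, true)) {
        inverted = e + 1;
        break;
      }
      const double J = arma::det(F);
      if (J < min_detF) min_detF = J;
      if (J > max_detF) max_detF = J;

      energy += W * detJ0;
      fe += detJ0 * (dNdX * P.t()); // f_{a,i} += w P_{iJ} dNdX_{aJ}

      if (stiffness) {
        // A(9x9) = dP/dF by central differences
        arma::mat::fixed<9, 9> A;
        arma::mat33 Fp, Pp, Pm;
        double Wtmp;
        bool ok = true;
        for (int c = 0; c < 9 && ok; ++c) {
          const int ci = c % 3, cj = c / 3;
          Fp = F; Fp(ci, cj) += hfd;
          ok = point_stress(Fp, mp, fibs[e], Wtmp, Pp, true);
          if (!ok) break;
          Fp = F; Fp(ci, cj) -= hfd;
          ok = point_stress(Fp, mp, fibs[e], Wtmp, Pm, true);
          if (!ok) break;
          const arma::mat33 dP = (Pp - Pm) / (2.0 * hfd);
          for (int r = 0; r < 9; ++r) A(r, c) = dP(r % 3, r / 3);
        }
        if (!ok) { inverted = e + 1; break; }
        // Z (24 x 9): Z[(a,i),(k,L)] = delta_ik dNdX(a,L)
        // K_e += detJ0 * Z A Z^T, with dof order (node a, component i)
        arma::mat::fixed<24, 9> Z;
        Z.zeros();
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            for (int L = 0; L < 3; ++L)
              Z(3 * a + i, i + 3 * L) = dNdX(a, L);
        Ke += detJ0 * (Z * A * Z.t());
      }
    }
    if (inverted) break;
    for (int a = 0; a < 8; ++a) force.row(elems(e, a) - 1) += fe.row(a);
    if (stiffness) {
      // symmetrise (FD noise) and store column-major
      Ke = 0.5 * (Ke + Ke.t());
      std::copy(Ke.begin(), Ke.end(), kvals.begin() + (size_t)e * 576);
    }
  }

  return List::create(_["energy"] = energy, _["force"] = force,
                      _["kvals"] = kvals, _["min_detF"] = min_detF,
                      _["max_detF"] = max_detF, _["inverted"] = inverted);
}

// Cauchy stress per Gauss point (rows: element-major, 8 gp each; columns:
// 3x3 column-major), for patch tests and inspection.
// [[Rcpp::export]]
arma::mat fem_gp_cauchy(const arma::mat &nodes, const arma::imat &elems,
                        const arma::mat &x, const List &pars,
                        const IntegerVector &fib_elem,
                        const NumericMatrix &fib_dir,
                        const NumericVector &fib_act) {
  const MatPars mp = read_pars(pars);
  const int ne = elems.n_rows;
  auto fibs = fibres_by_element(ne, fib_elem, fib_dir, fib_act);
  arma::mat out(ne * 8, 9);
  arma::mat::fixed<8, 3> dN;
  for (int e = 0; e < ne; ++e) {
    arma::mat::fixed<8, 3> Xe, xe;
    for (int a = 0; a < 8; ++a) {
      Xe.row(a) = nodes.row(elems(e, a) - 1);
      xe.row(a) = x.row(elems(e, a) - 1);
    }
    for (int g = 0; g < 8; ++g) {
      const double xi = (g & 1) ? GP : -GP;
      const double eta = (g & 2) ? GP : -GP;
      const double ze = (g & 4) ? GP : -GP;
      shape_grad(xi, eta, ze, dN);
      const arma::mat dNdX = dN * arma::inv(Xe.t() * dN);
      const arma::mat33 F = xe.t() * dNdX;
      double W;
      arma::mat33 P;
      if (!point_stress(F, mp, fibs[e], W, P, true)) {
        stop("inverted configuration at element %d", e + 1);
      }
      const arma::mat33 sig = (P * F.t()) / arma::det(F);
      for (int c = 0; c < 9; ++c) out(e * 8 + g, c) = sig(c % 3, c / 3);
    }
  }
  return out;
}
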