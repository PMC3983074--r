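// Scoring and pose-decoding kernels. A DockContext bundles everything that
// is constant across the evaluations of one ligand/receptor/cavity/restraint
// combination (pair parameters, polar site tables, exclusion masks, cavity
// points, reference intramolecular energies); the search loop then scores a
// chromosome with a single call. All angles crossing this interface are
// degrees; distances Angstroms. Atom indices arriving from R are 1-based and
// converted here.

#include <RcppArmadillo.h>
#include <functional>
#include <array>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double DEG = 57.29577951308232;

// ---------------------------------------------------------------- geometry

static arma::mat axisAngle(const arma::vec3& axisIn, double angleDeg) {
  arma::vec3 a = axisIn;
  double n = arma::norm(a);
  arma::mat R(3, 3, arma::fill::eye);
  if (n < 1e-12 || angleDeg == 0.0) return R;
  a /= n;
  double t = angleDeg / DEG, c = std::cos(t), s = std::sin(t), C = 1.0 - c;
  R(0,0) = c + a(0)*a(0)*C;      R(0,1) = a(0)*a(1)*C - a(2)*s; R(0,2) = a(0)*a(2)*C + a(1)*s;
  R(1,0) = a(1)*a(0)*C + a(2)*s; R(1,1) = c + a(1)*a(1)*C;      R(1,2) = a(1)*a(2)*C - a(0)*s;
  R(2,0) = a(2)*a(0)*C - a(1)*s; R(2,1) = a(2)*a(1)*C + a(0)*s; R(2,2) = c + a(2)*a(2)*C;
  return R;
}

static double dihedralAngleC(const arma::mat& X, int a, int b, int c, int d) {
  arma::vec3 b1 = X.row(b).t() - X.row(a).t();
  arma::vec3 b2 = X.row(c).t() - X.row(b).t();
  arma::vec3 b3 = X.row(d).t() - X.row(c).t();
  arma::vec3 n1 = arma::cross(b1, b2);
  arma::vec3 n2 = arma::cross(b2, b3);
  arma::vec3 m1 = arma::cross(n1, b2);
  double x = arma::dot(n1, n2);
  double y = arma::dot(m1, n2) / arma::norm(b2);
  return std::atan2(y, x) * DEG;
}

struct DihSpec {
  int a, b, c, d;
  std::vector<int> set;  // 0-based rotated atom indices
  double barrier;        // torsional barrier (3-fold), score units
};

static void setDihedralC(arma::mat& X, const DihSpec& dh, double angleDeg) {
  double cur = dihedralAngleC(X, dh.a, dh.b, dh.c, dh.d);
  double delta = angleDeg - cur;
  // right-hand rotation about b->c decreases the measured torsion
  arma::vec3 axis = X.row(dh.c).t() - X.row(dh.b).t();
  arma::mat R = axisAngle(axis, -delta);
  arma::vec3 pivot = X.row(dh.b).t();
  for (size_t k = 0; k < dh.set.size(); ++k) {
    int i = dh.set[k];
    arma::vec3 p = X.row(i).t() - pivot;
    X.row(i) = (R * p + pivot).t();
  }
}

// Principal axes (rows), ordered by decreasing moment, signs fixed so that
// the atom with the largest |projection| projects positively (first two
// axes; ties resolved to the first such atom), third axis = cross product.
// Must mirror principalAxes() on the R side exactly.
static arma::mat principalAxesC(const arma::mat& Xc) {
  arma::mat S = (Xc.t() * Xc) / (double)Xc.n_rows;
  arma::vec eval; arma::mat evec;
  arma::eig_sym(eval, evec, S);           // ascending
  arma::mat A(3, 3);
  A.row(0) = evec.col(2).t();
  A.row(1) = evec.col(1).t();
  A.row(2) = evec.col(0).t();
  for (int k = 0; k < 2; ++k) {
    arma::vec pr = Xc * A.row(k).t();
    arma::uword imax = 0; double best = -1.0;
    for (arma::uword i = 0; i < pr.n_elem; ++i)
      if (std::abs(pr(i)) > best) { best = std::abs(pr(i)); imax = i; }
    if (best > 1e-12 && pr(imax) < 0) A.row(k) = -A.row(k);
  }
  arma::vec3 a1 = A.row(0).t(), a2 = A.row(1).t();
  A.row(2) = arma::cross(a1, a2).t();
  return A;
}

static arma::mat eulerMatrixC(double h, double a, double b) {
  double ch = std::cos(h / DEG), sh = std::sin(h / DEG);
  double ca = std::cos(a / DEG), sa = std::sin(a / DEG);
  double cb = std::cos(b / DEG), sb = std::sin(b / DEG);
  arma::mat Rz = {{ch, -sh, 0}, {sh, ch, 0}, {0, 0, 1}};
  arma::mat Ry = {{ca, 0, sa}, {0, 1, 0}, {-sa, 0, ca}};
  arma::mat Rx = {{1, 0, 0}, {0, cb, -sb}, {0, sb, cb}};
  return Rz * Ry * Rx;
}

// ------------------------------------------------------------ energy terms

static inline double vdwE(double r, double r0, double eps, double n,
                          double m, double cap) {
  double q = r0 / r;
  double e = eps * (std::pow(q, n) - 2.0 * std::pow(q, m));
  return e > cap ? cap : e;
}

// trapezoidal distance ramp: 0 below lo-tol, 1 on [lo, hi], 0 above hi+tol
static inline double rampDist(double d, double lo, double hi, double tol) {
  if (d <= lo - tol || d >= hi + tol) return 0.0;
  if (d < lo) return (d - (lo - tol)) / tol;
  if (d > hi) return ((hi + tol) - d) / tol;
  return 1.0;
}

// one-sided contact ramp for same-polarity repulsion: 1 up to hi, 0 beyond
static inline double rampContact(double d, double hi, double tol) {
  if (d >= hi + tol) return 0.0;
  if (d <= hi) return 1.0;
  return ((hi + tol) - d) / tol;
}

// angular ramp: 1 above edge, falling linearly to 0 at edge - tol
static inline double rampAngle(double theta, double edge, double tol) {
  if (theta >= edge) return 1.0;
  if (theta <= edge - tol) return 0.0;
  return (theta - (edge - tol)) / tol;
}

static inline double angleDegC(const arma::vec3& p, const arma::vec3& q,
                               const arma::vec3& r) {
  arma::vec3 u = p - q, v = r - q;
  double c = arma::dot(u, v) / (arma::norm(u) * arma::norm(v) + 1e-300);
  if (c > 1) c = 1; if (c < -1) c = -1;
  return std::acos(c) * DEG;
}

struct PolarSite {
  int atom;      // heavy donor / acceptor / metal atom (0-based)
  int aux;       // donor: attached polar H; acceptor: root heavy (-1 none)
  int kind;      // 0 donor, 1 acceptor, 2 metal
  bool charged;
  bool ambi;     // atom is both donor and acceptor (e.g. hydroxyl O):
                 // exempt from same-polarity repulsion
};

struct PolarParams {
  double lo, hi, dtol, aDonorEdge, aAccEdge, atol, chargedScale;
  bool repulsive;
};

// polar sum between two site lists living on coordinate sets XA / XB.
// exclDist: graph-distance matrix (or empty) for intra evaluation; pairs at
// graph distance <= 3 are skipped. Attractive hydrogen-bond terms are
// aggregated by exclusive best pairing (greedy matching): every donor forms
// at most one hydrogen bond and every acceptor accepts at most one, which
// prevents a single polar group from saturating several partners at once.
struct HBondCand { double e; int da, ab; };

static double polarSum(const std::vector<PolarSite>& SA, const arma::mat& XA,
                       const std::vector<PolarSite>& SB, const arma::mat& XB,
                       const PolarParams& pp, const arma::imat* exclDist,
                       bool sameMol) {
  double e = 0.0;
  std::vector<HBondCand> cands;
  for (size_t ia = 0; ia < SA.size(); ++ia) {
    for (size_t ib = 0; ib < SB.size(); ++ib) {
      if (sameMol && ib <= ia) continue;
      const PolarSite& A = SA[ia];
      const PolarSite& B = SB[ib];
      if (exclDist && (*exclDist)(A.atom, B.atom) <= 3) continue;
      double mul = (A.charged && B.charged) ? pp.chargedScale : 1.0;
      bool donorA = A.kind == 0 || A.kind == 2;
      bool donorB = B.kind == 0 || B.kind == 2;
      bool accA = A.kind == 1, accB = B.kind == 1;
      double d = arma::norm(XA.row(A.atom) - XB.row(B.atom));
      if ((donorA && accB) || (accA && donorB)) {
        const PolarSite& D = donorA ? A : B;
        const PolarSite& Ac = donorA ? B : A;
        const arma::mat& XD = donorA ? XA : XB;
        const arma::mat& XAc = donorA ? XB : XA;
        double fd = rampDist(d, pp.lo, pp.hi, pp.dtol);
        if (fd <= 0) continue;
        double fth = 1.0, fph = 1.0;
        if (D.kind == 0 && D.aux >= 0) {
          // theta: donor-heavy -- H ... acceptor, ideal linear
          double th = angleDegC(XD.row(D.atom).t(), XD.row(D.aux).t(),
                                XAc.row(Ac.atom).t());
          fth = rampAngle(th, pp.aDonorEdge, pp.atol);
          if (Ac.aux >= 0) {
            double ph = angleDegC(XAc.row(Ac.aux).t(), XAc.row(Ac.atom).t(),
                                  XD.row(D.aux).t());
            fph = rampAngle(ph, pp.aAccEdge, pp.atol);
          }
        } else if (Ac.aux >= 0) {  // metal donor: acceptor angle only
          double ph = angleDegC(XAc.row(Ac.aux).t(), XAc.row(Ac.atom).t(),
                                XD.row(D.atom).t());
          fph = rampAngle(ph, pp.aAccEdge, pp.atol);
        }
        double val = mul * fd * fth * fph;
        if (val > 0) {
          HBondCand c;
          c.e = -val;
          c.da = donorA ? (int)ia : (int)(SA.size() + ib);
          c.ab = donorA ? (int)(SA.size() + ib) : (int)ia;
          cands.push_back(c);
        }
      } else if (pp.repulsive && !A.ambi && !B.ambi &&
                 ((A.kind == 0 && B.kind == 0) || (accA && accB))) {
        e += mul * rampContact(d, pp.hi, pp.dtol);
      }
    }
  }
  // greedy exclusive matching of donor and acceptor roles
  std::sort(cands.begin(), cands.end(),
            [](const HBondCand& a, const HBondCand& b) { return a.e < b.e; });
  std::vector<bool> usedD, usedA;
  usedD.assign(SA.size() + SB.size(), false);
  usedA.assign(SA.size() + SB.size(), false);
  for (size_t k = 0; k < cands.size(); ++k) {
    if (usedD[cands[k].da] || usedA[cands[k].ab]) continue;
    usedD[cands[k].da] = true;
    usedA[cands[k].ab] = true;
    e += cands[k].e;
  }
  return e;
}

// ---------------------------------------------------------------- context

struct Ph4Restraint {
  arma::vec3 center;
  double radius, weight;
  bool mandatory;
  std::vector<int> atomCands;   // 0-based ligand atoms
  std::vector<int> ringCands;   // indices into rings
};

struct DistRestraint {
  std::vector<int> lig, rec;    // 0-based
  double bound, weight;
  bool upper;
};

struct GridSet {
  arma::vec3 origin;
  double spacing;
  int nx, ny, nz;
  std::vector<arma::cube> grids;   // one per ligand class
  std::vector<int> atomClass;      // ligand atom -> grid index (-1 skip: H?)
};

struct DockContext {
  arma::mat L0;                 // ligand input conformation
  arma::mat Rec0;               // receptor coordinates
  std::vector<DihSpec> ligDih, recDih;
  std::vector<int> ligHeavy;    // 0-based
  arma::mat R0p, EPSp;          // nL x nR vdW pair parameters
  // intra-ligand vdW pair list
  std::vector<int> ipI, ipJ;
  arma::vec ipR0, ipEps, ipScale;
  // receptor site vdW pair list (moving-atom pairs)
  std::vector<int> spI, spJ;
  arma::vec spR0, spEps, spScale;
  std::vector<PolarSite> ligPol, recPol;
  arma::imat ligDist;           // ligand graph distances (capped)
  // SASA / desolvation
  bool haveDesolv = false;
  arma::vec radL, radR, pL, pR, wL, wR;  // radii+rsolv baked separately
  double rsolv = 1.4, sasaFloor = 0.1;
  arma::imat recDist;           // receptor graph distances (capped, for pij)
  // restraints
  std::vector<Ph4Restraint> ph4;
  int nOpt = 0;
  std::vector<DistRestraint> distRes;
  arma::mat cavPts;
  double cavSpacing = 0.5, cavWeight = 1.0;
  std::vector<std::vector<int>> rings;   // ligand rings (0-based)
  // tether
  bool tethered = false;
  std::vector<int> tetherAtoms;  // 0-based
  // reference (input conformation) raw intra components
  double refIntraVdw48 = 0, refIntraVdw612 = 0, refIntraPol = 0,
         refIntraDih = 0;
  double refSiteVdw48 = 0, refSiteVdw612 = 0, refSitePol = 0,
         refSiteDih = 0;
  // weights and polar configuration
  double wInter = 1, wIntra = 1, wSite = 1, wRestraint = 1;
  double wVdw = 1, wPolar = 1, wDesolv = 1, wDihedral = 1;
  double vdwCap = 100.0;
  PolarParams pol;
  // vdW grids (optional), keyed by form
  bool haveGrid48 = false, haveGrid612 = false;
  GridSet grid48, grid612;
};

static std::vector<DihSpec> readDihList(List lst) {
  std::vector<DihSpec> out;
  for (int k = 0; k < lst.size(); ++k) {
    List d = lst[k];
    IntegerVector at = d["atoms"];
    IntegerVector st = d["set"];
    DihSpec sp;
    sp.a = at[0] - 1; sp.b = at[1] - 1; sp.c = at[2] - 1; sp.d = at[3] - 1;
    for (int i = 0; i < st.size(); ++i) sp.set.push_back(st[i] - 1);
    sp.barrier = as<double>(d["barrier"]);
    out.push_back(sp);
  }
  return out;
}

static std::vector<PolarSite> readSites(List lst) {
  std::vector<PolarSite> out;
  IntegerVector atom = lst["atom"], aux = lst["aux"], kind = lst["kind"];
  LogicalVector ch = lst["charged"], am = lst["ambi"];
  for (int k = 0; k < atom.size(); ++k) {
    PolarSite s;
    s.atom = atom[k] - 1;
    s.aux = aux[k] > 0 ? aux[k] - 1 : -1;
    s.kind = kind[k];
    s.charged = ch[k];
    s.ambi = am[k];
    out.push_back(s);
  }
  return out;
}

static GridSet readGridSet(List g) {
  GridSet gs;
  NumericVector o = g["origin"];
  gs.origin = arma::vec3({o[0], o[1], o[2]});
  gs.spacing = as<double>(g["spacing"]);
  IntegerVector dims = g["dims"];
  gs.nx = dims[0]; gs.ny = dims[1]; gs.nz = dims[2];
  List arrs = g["grids"];
  for (int k = 0; k < arrs.size(); ++k) {
    NumericVector a = arrs[k];
    arma::cube c(gs.nx, gs.ny, gs.nz);
    std::copy(a.begin(), a.end(), c.memptr());
    gs.grids.push_back(c);
  }
  IntegerVector ac = g["atomClass"];
  for (int k = 0; k < ac.size(); ++k) gs.atomClass.push_back(ac[k] - 1);
  return gs;
}

// [[Rcpp::export]]
SEXP cpp_build_context(List args) {
  DockContext* ctx = new DockContext();
  ctx->L0 = as<arma::mat>(args["L0"]);
  ctx->Rec0 = as<arma::mat>(args["Rec0"]);
  ctx->ligDih = readDihList(args["ligDih"]);
  ctx->recDih = readDihList(args["recDih"]);
  IntegerVector lh = args["ligHeavy"];
  for (int k = 0; k < lh.size(); ++k) ctx->ligHeavy.push_back(lh[k] - 1);
  ctx->R0p = as<arma::mat>(args["R0pair"]);
  ctx->EPSp = as<arma::mat>(args["EPSpair"]);
  List ip = args["intraPairs"];
  {
    IntegerVector i = ip["i"], j = ip["j"];
    NumericVector r0 = ip["r0"], eps = ip["eps"], sc = ip["scale"];
    for (int k = 0; k < i.size(); ++k) {
      ctx->ipI.push_back(i[k] - 1);
      ctx->ipJ.push_back(j[k] - 1);
    }
    ctx->ipR0 = as<arma::vec>(r0);
    ctx->ipEps = as<arma::vec>(eps);
    ctx->ipScale = as<arma::vec>(sc);
  }
  List sp = args["sitePairs"];
  {
    IntegerVector i = sp["i"], j = sp["j"];
    NumericVector r0 = sp["r0"], eps = sp["eps"], sc = sp["scale"];
    for (int k = 0; k < i.size(); ++k) {
      ctx->spI.push_back(i[k] - 1);
      ctx->spJ.push_back(j[k] - 1);
    }
    ctx->spR0 = as<arma::vec>(r0);
    ctx->spEps = as<arma::vec>(eps);
    ctx->spScale = as<arma::vec>(sc);
  }
  ctx->ligPol = readSites(args["ligPolar"]);
  ctx->recPol = readSites(args["recPolar"]);
  ctx->ligDist = as<arma::imat>(args["ligDist"]);

  List cfg = args["config"];
  ctx->wInter = as<double>(cfg["inter"]);
  ctx->wIntra = as<double>(cfg["intra"]);
  ctx->wSite = as<double>(cfg["site"]);
  ctx->wRestraint = as<double>(cfg["restraint"]);
  ctx->wVdw = as<double>(cfg["vdw"]);
  ctx->wPolar = as<double>(cfg["polar"]);
  ctx->wDesolv = as<double>(cfg["desolv"]);
  ctx->wDihedral = as<double>(cfg["dihedral"]);
  ctx->vdwCap = as<double>(cfg["vdwCap"]);
  ctx->pol.lo = as<double>(cfg["polarLo"]);
  ctx->pol.hi = as<double>(cfg["polarHi"]);
  ctx->pol.dtol = as<double>(cfg["polarDistTol"]);
  ctx->pol.aDonorEdge = as<double>(cfg["donorAngleEdge"]);
  ctx->pol.aAccEdge = as<double>(cfg["acceptorAngleEdge"]);
  ctx->pol.atol = as<double>(cfg["polarAngleTol"]);
  ctx->pol.chargedScale = as<double>(cfg["chargedScale"]);
  ctx->pol.repulsive = true;

  if (args.containsElementNamed("desolv") &&
      !Rf_isNull(args["desolv"])) {
    List ds = args["desolv"];
    ctx->haveDesolv = true;
    ctx->radL = as<arma::vec>(ds["radL"]);
    ctx->radR = as<arma::vec>(ds["radR"]);
    ctx->pL = as<arma::vec>(ds["pL"]);
    ctx->pR = as<arma::vec>(ds["pR"]);
    ctx->wL = as<arma::vec>(ds["wL"]);
    ctx->wR = as<arma::vec>(ds["wR"]);
    ctx->rsolv = as<double>(ds["rsolv"]);
    ctx->recDist = as<arma::imat>(ds["recDist"]);
  }

  List rings = args["rings"];
  for (int k = 0; k < rings.size(); ++k) {
    IntegerVector r = rings[k];
    std::vector<int> rr;
    for (int i = 0; i < r.size(); ++i) rr.push_back(r[i] - 1);
    ctx->rings.push_back(rr);
  }
  List ph4 = args["ph4"];
  for (int k = 0; k < ph4.size(); ++k) {
    List p = ph4[k];
    Ph4Restraint r;
    NumericVector c = p["center"];
    r.center = arma::vec3({c[0], c[1], c[2]});
    r.radius = as<double>(p["radius"]);
    r.weight = as<double>(p["weight"]);
    r.mandatory = as<bool>(p["mandatory"]);
    IntegerVector ac = p["atoms"];
    for (int i = 0; i < ac.size(); ++i) r.atomCands.push_back(ac[i] - 1);
    IntegerVector rc = p["rings"];
    for (int i = 0; i < rc.size(); ++i) r.ringCands.push_back(rc[i] - 1);
    ctx->ph4.push_back(r);
  }
  ctx->nOpt = as<int>(args["nOpt"]);
  List dr = args["distRestraints"];
  for (int k = 0; k < dr.size(); ++k) {
    List p = dr[k];
    DistRestraint r;
    IntegerVector li = p["lig"], re = p["rec"];
    for (int i = 0; i < li.size(); ++i) r.lig.push_back(li[i] - 1);
    for (int i = 0; i < re.size(); ++i) r.rec.push_back(re[i] - 1);
    r.bound = as<double>(p["bound"]);
    r.weight = as<double>(p["weight"]);
    r.upper = as<bool>(p["upper"]);
    ctx->distRes.push_back(r);
  }
  ctx->cavPts = as<arma::mat>(args["cavPts"]);
  ctx->cavSpacing = as<double>(args["cavSpacing"]);
  ctx->cavWeight = as<double>(args["cavWeight"]);

  ctx->tethered = as<bool>(args["tethered"]);
  if (ctx->tethered) {
    IntegerVector ta = args["tetherAtoms"];
    for (int k = 0; k < ta.size(); ++k) ctx->tetherAtoms.push_back(ta[k] - 1);
  }
  if (args.containsElementNamed("grid48") && !Rf_isNull(args["grid48"])) {
    ctx->grid48 = readGridSet(args["grid48"]);
    ctx->haveGrid48 = true;
  }
  if (args.containsElementNamed("grid612") && !Rf_isNull(args["grid612"])) {
    ctx->grid612 = readGridSet(args["grid612"]);
    ctx->haveGrid612 = true;
  }
  XPtr<DockContext> ptr(ctx, true);
  // reference intramolecular components are filled by cpp_finalize_context
  return ptr;
}

// ---- component evaluation helpers over explicit coordinates

static double intraVdwC(const DockContext* ctx, const arma::mat& L,
                        double n, double m) {
  double e = 0;
  for (size_t k = 0; k < ctx->ipI.size(); ++k) {
    double d = arma::norm(L.row(ctx->ipI[k]) - L.row(ctx->ipJ[k]));
    e += ctx->ipScale(k) * vdwE(d, ctx->ipR0(k), ctx->ipEps(k), n, m,
                                ctx->vdwCap);
  }
  return e;
}

static double siteVdwC(const DockContext* ctx, const arma::mat& R,
                       double n, double m) {
  double e = 0;
  for (size_t k = 0; k < ctx->spI.size(); ++k) {
    double d = arma::norm(R.row(ctx->spI[k]) - R.row(ctx->spJ[k]));
    e += ctx->spScale(k) * vdwE(d, ctx->spR0(k), ctx->spEps(k), n, m,
                                ctx->vdwCap);
  }
  return e;
}

static double dihedralEnergyC(const std::vector<DihSpec>& dihs,
                              const arma::mat& X) {
  double e = 0;
  for (size_t k = 0; k < dihs.size(); ++k) {
    double phi = dihedralAngleC(X, dihs[k].a, dihs[k].b, dihs[k].c,
                                dihs[k].d) / DEG;
    e += 0.5 * dihs[k].barrier * (1.0 + std::cos(3.0 * phi));
  }
  return e;
}

static double interVdwDirect(const DockContext* ctx, const arma::mat& L,
                             const arma::mat& R, double n, double m) {
  double e = 0;
  for (arma::uword i = 0; i < L.n_rows; ++i) {
    for (arma::uword j = 0; j < R.n_rows; ++j) {
      double dx = L(i,0)-R(j,0), dy = L(i,1)-R(j,1), dz = L(i,2)-R(j,2);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      e += vdwE(d, ctx->R0p(i,j), ctx->EPSp(i,j), n, m, ctx->vdwCap);
    }
  }
  return e;
}

static double trilinear(const arma::cube& g, const arma::vec3& origin,
                        double h, const arma::vec3& p, double fallback) {
  double fx = (p(0) - origin(0)) / h;
  double fy = (p(1) - origin(1)) / h;
  double fz = (p(2) - origin(2)) / h;
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
      iz = (int)std::floor(fz);
  if (ix < 0 || iy < 0 || iz < 0 || ix + 1 >= (int)g.n_rows ||
      iy + 1 >= (int)g.n_cols || iz + 1 >= (int)g.n_slices)
    return fallback;
  double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  double v = 0;
  for (int dx = 0; dx <= 1; ++dx)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dz = 0; dz <= 1; ++dz)
        v += g(ix+dx, iy+dy, iz+dz) *
             (dx ? tx : 1-tx) * (dy ? ty : 1-ty) * (dz ? tz : 1-tz);
  return v;
}

static double interVdwGrid(const DockContext* ctx, const arma::mat& L,
                           const GridSet& gs) {
  double e = 0;
  for (arma::uword i = 0; i < L.n_rows; ++i) {
    int cls = gs.atomClass[i];
    if (cls < 0) continue;
    e += trilinear(gs.grids[cls], gs.origin, gs.spacing, L.row(i).t(),
                   ctx->vdwCap);
  }
  return e;
}

// Hasel-style pairwise SASA for a merged coordinate set.
static arma::vec haselC(const arma::mat& X, const arma::vec& rad,
                        const arma::vec& p, double rsolv,
                        const std::function<double(int,int)>& pij,
                        double dfloor) {
  int n = X.n_rows;
  arma::vec S(n), A(n);
  for (int i = 0; i < n; ++i) {
    double R = rad(i) + rsolv;
    S(i) = 4.0 * M_PI * R * R;
    A(i) = S(i);
  }
  for (int i = 0; i < n; ++i) {
    double Ri = rad(i) + rsolv;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double pw = pij(i, j);
      if (pw <= 0) continue;
      double d = arma::norm(X.row(i) - X.row(j));
      if (d < dfloor) d = dfloor;
      double Rj = rad(j) + rsolv;
      if (d >= Ri + Rj) continue;
      double b = M_PI * Ri * (Ri + Rj - d) * (1.0 + (Rj - Ri) / d);
      if (b < 0) b = 0;
      if (b > S(i)) b = S(i);
      double f = 1.0 - p(i) * pw * b / S(i);
      if (f < 0) f = 0;
      A(i) *= f;
    }
  }
  return A;
}

static double pijFromDist(int gd) {
  // connectivity classes (1-2, 1-3, distant), calibrated in-package
  // against numerical sphere-sampling areas
  if (gd == 1) return 1.0296;
  if (gd == 2) return 0.0;
  return 0.2631;
}

static double desolvC(const DockContext* ctx, const arma::mat& L,
                      const arma::mat& R) {
  int nL = L.n_rows, nR = R.n_rows;
  arma::mat X(nL + nR, 3);
  X.rows(0, nL - 1) = L;
  X.rows(nL, nL + nR - 1) = R;
  arma::vec rad(nL + nR), p(nL + nR);
  rad.subvec(0, nL - 1) = ctx->radL;
  rad.subvec(nL, nL + nR - 1) = ctx->radR;
  p.subvec(0, nL - 1) = ctx->pL;
  p.subvec(nL, nL + nR - 1) = ctx->pR;
  const arma::imat& dl = ctx->ligDist;
  const arma::imat& dr = ctx->recDist;
  auto pijAll = [&](int i, int j) {
    if (i < nL && j < nL) return pijFromDist(dl(i, j));
    if (i >= nL && j >= nL) return pijFromDist(dr(i - nL, j - nL));
    return 0.3516;
  };
  arma::vec Ab = haselC(X, rad, p, ctx->rsolv, pijAll, ctx->sasaFloor);
  auto pijL = [&](int i, int j) { return pijFromDist(dl(i, j)); };
  arma::vec Afl = haselC(L, ctx->radL, ctx->pL, ctx->rsolv, pijL,
                         ctx->sasaFloor);
  auto pijR = [&](int i, int j) { return pijFromDist(dr(i, j)); };
  arma::vec Afr = haselC(R, ctx->radR, ctx->pR, ctx->rsolv, pijR,
                         ctx->sasaFloor);
  double e = 0;
  for (int i = 0; i < nL; ++i) e += ctx->wL(i) * (Ab(i) - Afl(i));
  for (int i = 0; i < nR; ++i) e += ctx->wR(i) * (Ab(nL + i) - Afr(i));
  return e;
}

static double minDistToPoints(const arma::mat& pts, const arma::vec3& p) {
  double best = std::numeric_limits<double>::infinity();
  for (arma::uword k = 0; k < pts.n_rows; ++k) {
    double dx = pts(k,0)-p(0), dy = pts(k,1)-p(1), dz = pts(k,2)-p(2);
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 < best) best = d2;
  }
  return std::sqrt(best);
}

static double cavityPenaltyC(const DockContext* ctx, const arma::mat& L) {
  if (ctx->cavPts.n_rows == 0 || ctx->cavWeight == 0) return 0.0;
  double e = 0, half = 0.5 * ctx->cavSpacing;
  for (size_t k = 0; k < ctx->ligHeavy.size(); ++k) {
    arma::vec3 p = L.row(ctx->ligHeavy[k]).t();
    double d = minDistToPoints(ctx->cavPts, p);
    if (d > half) e += ctx->cavWeight * d * d;
  }
  return e;
}

static double ph4PenaltyC(const DockContext* ctx, const arma::mat& L) {
  if (ctx->ph4.empty()) return 0.0;
  double mand = 0;
  std::vector<double> opt;
  for (size_t k = 0; k < ctx->ph4.size(); ++k) {
    const Ph4Restraint& r = ctx->ph4[k];
    double best = std::numeric_limits<double>::infinity();
    for (size_t i = 0; i < r.atomCands.size(); ++i) {
      double d = arma::norm(L.row(r.atomCands[i]).t() - r.center);
      if (d < best) best = d;
    }
    for (size_t i = 0; i < r.ringCands.size(); ++i) {
      const std::vector<int>& ring = ctx->rings[r.ringCands[i]];
      arma::vec3 c = arma::zeros<arma::vec>(3);
      for (size_t q = 0; q < ring.size(); ++q) c += L.row(ring[q]).t();
      c /= (double)ring.size();
      double d = arma::norm(c - r.center);
      if (d < best) best = d;
    }
    double pen;
    if (!std::isfinite(best)) {
      pen = 1e9;  // feature absent: should have been screened out
    } else {
      double excess = best - r.radius;
      pen = excess > 0 ? r.weight * excess * excess : 0.0;
    }
    if (r.mandatory) mand += pen; else opt.push_back(pen);
  }
  std::sort(opt.begin(), opt.end());
  double e = mand;
  for (int k = 0; k < ctx->nOpt && k < (int)opt.size(); ++k) e += opt[k];
  return e;
}

static double nmrPenaltyC(const DockContext* ctx, const arma::mat& L,
                          const arma::mat& R) {
  double e = 0;
  for (size_t k = 0; k < ctx->distRes.size(); ++k) {
    const DistRestraint& r = ctx->distRes[k];
    double best = std::numeric_limits<double>::infinity();
    for (size_t i = 0; i < r.lig.size(); ++i)
      for (size_t j = 0; j < r.rec.size(); ++j) {
        double d = arma::norm(L.row(r.lig[i]) - R.row(r.rec[j]));
        if (d < best) best = d;
      }
    double v = r.upper ? best - r.bound : r.bound - best;
    if (v > 0) e += r.weight * v * v;
  }
  return e;
}

// stage: numeric vector [n, m, tolScale, dihScale, repulsive, useDesolv,
//                        useGrid]
static NumericVector scoreCoords(const DockContext* ctx, const arma::mat& L,
                                 const arma::mat& R,
                                 const NumericVector& stage) {
  double n = stage[0], m = stage[1], tolScale = stage[2],
         dihScale = stage[3];
  bool repulsive = stage[4] != 0, useDesolv = stage[5] != 0,
       useGrid = stage[6] != 0;
  PolarParams pp = ctx->pol;
  pp.dtol *= tolScale;
  pp.atol *= tolScale;
  pp.repulsive = repulsive;

  bool form48 = (n == 8.0);
  double interVdw;
  if (useGrid) {
    const GridSet& gs = form48 ? ctx->grid48 : ctx->grid612;
    interVdw = interVdwGrid(ctx, L, gs);
  } else {
    interVdw = interVdwDirect(ctx, L, R, n, m);
  }
  double interPol = polarSum(ctx->ligPol, L, ctx->recPol, R, pp, nullptr,
                             false);
  double interDes = (useDesolv && ctx->haveDesolv) ? desolvC(ctx, L, R) : 0;
  double inter = ctx->wVdw * interVdw + ctx->wPolar * interPol +
                 ctx->wDesolv * interDes;

  double intraVdw = intraVdwC(ctx, L, n, m);
  double intraPol = polarSum(ctx->ligPol, L, ctx->ligPol, L, pp,
                             &ctx->ligDist, true);
  double intraDih = dihedralEnergyC(ctx->ligDih, L);
  double refVdw = form48 ? ctx->refIntraVdw48 : ctx->refIntraVdw612;
  double intra = ctx->wVdw * (intraVdw - refVdw) +
                 ctx->wPolar * (intraPol - ctx->refIntraPol) +
                 ctx->wDihedral * dihScale * (intraDih - ctx->refIntraDih);

  double siteVdw = siteVdwC(ctx, R, n, m);
  double siteDih = dihedralEnergyC(ctx->recDih, R);
  double refSVdw = form48 ? ctx->refSiteVdw48 : ctx->refSiteVdw612;
  double site = ctx->wVdw * (siteVdw - refSVdw) +
                ctx->wDihedral * (siteDih - ctx->refSiteDih);

  double cav = cavityPenaltyC(ctx, L);
  double ph4 = ph4PenaltyC(ctx, L);
  double nmr = nmrPenaltyC(ctx, L, R);
  double restraint = cav + ph4 + nmr;

  double total = ctx->wInter * inter + ctx->wIntra * intra +
                 ctx->wSite * site + ctx->wRestraint * restraint;
  return NumericVector::create(
    _["total"] = total, _["inter"] = inter, _["intra"] = intra,
    _["site"] = site, _["restraint"] = restraint,
    _["inter.vdw"] = interVdw, _["inter.polar"] = interPol,
    _["inter.desolv"] = interDes,
    _["intra.vdw"] = intraVdw - refVdw,
    _["intra.polar"] = intraPol - ctx->refIntraPol,
    _["intra.dihedral"] = intraDih - ctx->refIntraDih,
    _["site.vdw"] = siteVdw - refSVdw,
    _["site.dihedral"] = siteDih - ctx->refSiteDih,
    _["restraint.cavity"] = cav, _["restraint.ph4"] = ph4,
    _["restraint.nmr"] = nmr);
}

// [[Rcpp::export]]
void cpp_finalize_context(SEXP ctxPtr) {
  XPtr<DockContext> ctx(ctxPtr);
  const arma::mat& L = ctx->L0;
  const arma::mat& R = ctx->Rec0;
  ctx->refIntraVdw48 = intraVdwC(ctx, L, 8, 4);
  ctx->refIntraVdw612 = intraVdwC(ctx, L, 12, 6);
  PolarParams pp = ctx->pol;
  ctx->refIntraPol = polarSum(ctx->ligPol, L, ctx->ligPol, L, pp,
                              &ctx->ligDist, true);
  ctx->refIntraDih = dihedralEnergyC(ctx->ligDih, L);
  ctx->refSiteVdw48 = siteVdwC(ctx, R, 8, 4);
  ctx->refSiteVdw612 = siteVdwC(ctx, R, 12, 6);
  ctx->refSiteDih = dihedralEnergyC(ctx->recDih, R);
}

// ------------------------------------------------------------- decoding

static void decodeChrom(const DockContext* ctx, const arma::vec& chrom,
                        arma::mat& L, arma::mat& R) {
  L = ctx->L0;
  int nLig = ctx->ligDih.size();
  for (int k = 0; k < nLig; ++k)
    setDihedralC(L, ctx->ligDih[k], chrom(6 + k));
  if (ctx->tethered) {
    // chromosome holds COM deviation + rotation vector (axis * degrees)
    arma::vec3 comT = arma::zeros<arma::vec>(3);
    for (size_t k = 0; k < ctx->tetherAtoms.size(); ++k)
      comT += L.row(ctx->tetherAtoms[k]).t();
    comT /= (double)ctx->tetherAtoms.size();
    arma::vec3 rv = {chrom(3), chrom(4), chrom(5)};
    double ang = arma::norm(rv);
    arma::mat Rr = axisAngle(rv, ang);
    arma::vec3 dev = {chrom(0), chrom(1), chrom(2)};
    for (arma::uword i = 0; i < L.n_rows; ++i) {
      arma::vec3 p = L.row(i).t() - comT;
      L.row(i) = (Rr * p + comT + dev).t();
    }
  } else {
    arma::rowvec com0 = arma::mean(L, 0);
    arma::mat Lc = L.each_row() - com0;
    arma::mat A0 = principalAxesC(Lc);
    arma::mat E = eulerMatrixC(chrom(3), chrom(4), chrom(5));
    arma::mat Rot = E * A0;
    arma::rowvec com = {chrom(0), chrom(1), chrom(2)};
    L = Lc * Rot.t();
    L.each_row() += com;
  }
  R = ctx->Rec0;
  for (size_t k = 0; k < ctx->recDih.size(); ++k)
    setDihedralC(R, ctx->recDih[k], chrom(6 + nLig + k));
}

// [[Rcpp::export]]
double cpp_score_chrom(SEXP ctxPtr, NumericVector chrom,
                       NumericVector stage) {
  XPtr<DockContext> ctx(ctxPtr);
  arma::vec ch = as<arma::vec>(chrom);
  arma::mat L, R;
  decodeChrom(ctx, ch, L, R);
  NumericVector v = scoreCoords(ctx, L, R, stage);
  return v[0];
}

// [[Rcpp::export]]
NumericVector cpp_score_chrom_full(SEXP ctxPtr, NumericVector chrom,
                                   NumericVector stage) {
  XPtr<DockContext> ctx(ctxPtr);
  arma::vec ch = as<arma::vec>(chrom);
  arma::mat L, R;
  decodeChrom(ctx, ch, L, R);
  return scoreCoords(ctx, L, R, stage);
}

// [[Rcpp::export]]
NumericMatrix cpp_decode_ligand(SEXP ctxPtr, NumericVector chrom) {
  XPtr<DockContext> ctx(ctxPtr);
  arma::vec ch = as<arma::vec>(chrom);
  arma::mat L, R;
  decodeChrom(ctx, ch, L, R);
  return wrap(L);
}

// [[Rcpp::export]]
NumericMatrix cpp_decode_receptor(SEXP ctxPtr, NumericVector chrom) {
  XPtr<DockContext> ctx(ctxPtr);
  arma::vec ch = as<arma::vec>(chrom);
  arma::mat L, R;
  decodeChrom(ctx, ch, L, R);
  return wrap(R);
}

// [[Rcpp::export]]
NumericVector cpp_score_coords(SEXP ctxPtr, NumericMatrix ligCoords,
                               NumericVector recDihAngles,
                               NumericVector stage) {
  XPtr<DockContext> ctx(ctxPtr);
  arma::mat L = as<arma::mat>(ligCoords);
  arma::mat R = ctx->Rec0;
  for (size_t k = 0; k < ctx->recDih.size(); ++k)
    setDihedralC(R, ctx->recDih[k], recDihAngles[k]);
  return scoreCoords(ctx, L, R, stage);
}

// ------------------------------------------------- standalone kernels

// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix points, NumericMatrix queries) {
  arma::mat P = as<arma::mat>(points);
  arma::mat Q = as<arma::mat>(queries);
  NumericVector out(Q.n_rows);
  for (arma::uword i = 0; i < Q.n_rows; ++i)
    out[i] = minDistToPoints(P, Q.row(i).t());
  return out;
}

// Summed receptor vdW field for one ligand class at a set of points.
// [[Rcpp::export]]
NumericVector cpp_vdw_field(NumericMatrix points, NumericMatrix recCoords,
                            NumericVector r0, NumericVector eps,
                            double n, double m, double cap) {
  arma::mat P = as<arma::mat>(points);
  arma::mat R = as<arma::mat>(recCoords);
  NumericVector out(P.n_rows);
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    double e = 0;
    for (arma::uword j = 0; j < R.n_rows; ++j) {
      double dx = P(i,0)-R(j,0), dy = P(i,1)-R(j,1), dz = P(i,2)-R(j,2);
      double d = std::sqrt(dx*dx + dy*dy + dz*dz);
      e += vdwE(d, r0[j], eps[j], n, m, cap);
    }
    out[i] = e;
  }
  return out;
}

// Per-atom Hasel-style SASA. pij supplied as a full matrix (0 = skip pair).
// [[Rcpp::export]]
NumericVector cpp_hasel_sasa(NumericMatrix X, NumericVector radii,
                             NumericVector p, NumericMatrix pij,
                             double rsolv, double dfloor) {
  arma::mat Xm = as<arma::mat>(X);
  arma::vec rad = as<arma::vec>(radii);
  arma::vec pv = as<arma::vec>(p);
  arma::mat pm = as<arma::mat>(pij);
  auto pf = [&](int i, int j) { return pm(i, j); };
  return wrap(haselC(Xm, rad, pv, rsolv, pf, dfloor));
}

// Euclidean distance transform of a cavity lattice: for every lattice point
// the distance to the nearest inside point (exact, brute force over inside
// points).
// [[Rcpp::export]]
NumericVector cpp_distance_lattice(LogicalVector inside, IntegerVector dims,
                                   double spacing) {
  int nx = dims[0], ny = dims[1];
  std::vector<std::array<int,3>> in;
  // R arrays are column-major with the first index fastest
  for (int t = 0; t < inside.size(); ++t) {
    if (inside[t]) {
      int i = t % nx, j = (t / nx) % ny, k = t / (nx * ny);
      in.push_back({i, j, k});
    }
  }
  NumericVector out(inside.size());
  for (int t = 0; t < inside.size(); ++t) {
    if (inside[t]) { out[t] = 0.0; continue; }
    int i = t % nx, j = (t / nx) % ny, k = t / (nx * ny);
    double best = std::numeric_limits<double>::infinity();
    for (size_t q = 0; q < in.size(); ++q) {
      double dx = i - in[q][0], dy = j - in[q][1], dz = k - in[q][2];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[t] = std::sqrt(best) * spacing;
  }
  return out;
}
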