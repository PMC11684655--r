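// Compiled right-hand sides for the detailed (12-variable) and simplified
// (2-variable) multi-compartment astrocyte models. Mirrors the reference
// R implementations; equivalence is asserted in the test suite.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Edge { int j, k; double g; }; // d[X]_j/dt += D * g * ([X]_k - [X]_j)

struct ModelCtx {
  int n;
  std::vector<double> av, rer;
  std::vector<Edge> edges;
  // parameters
  double faraday, cm, rtf;
  double d1, d2, d3, d5, a2, p_ip3r;
  double p_serca, k_serca, p_caerl;
  double p_ncx, k_ncx_na, k_ncx_ca, eta_ncx, ksat_ncx;
  double p_glut, k_glut;
  double p_nka, k_nka_na, k_nka_k;
  double g_nal, g_kl;
  double o_beta_glu, k_r_glu, k_p_glu, k_pi_glu;
  double o_beta_da, k_r_da, k_p_da, k_pi_da;
  double o_delta, kappa_delta, k_delta;
  double o_3k, k_d_3k, k_3_3k, omega_5p;
  double g_glu_decay, g_da_decay, rho_glu, rho_da;
  double d_ca, d_ip3, d_cae, d_caer, d_na, d_k, d_glu, d_da;
  bool include_er_currents;
  // simplified-model extras
  double h_avg, glu_scale, da_scale;
  std::vector<double> na_i0v, na_e0v, k_e0v; // rest values used by reduction
  double ca_e0, na_i0, na_e0, k_i0, k_e0, v0, ca_er0, ca_i0, ip3_0;
};

static double getp(const List& p, const char* nm) {
  return as<double>(p[nm]);
}

// [[Rcpp::export]]
SEXP build_context(const List morphGeom, const List params) {
  ModelCtx* c = new ModelCtx();
  NumericVector av = morphGeom["av"], rer = morphGeom["rer"];
  NumericMatrix G = morphGeom["G"];
  c->n = av.size();
  c->av.assign(av.begin(), av.end());
  c->rer.assign(rer.begin(), rer.end());
  for (int j = 0; j < c->n; ++j)
    for (int k = 0; k < c->n; ++k)
      if (G(j, k) != 0.0) c->edges.push_back({j, k, G(j, k)});
  const List& p = params;
  c->faraday = getp(p, "faraday"); c->cm = getp(p, "cm");
  c->rtf = getp(p, "rtf");
  c->d1 = getp(p, "d1"); c->d2 = getp(p, "d2"); c->d3 = getp(p, "d3");
  c->d5 = getp(p, "d5"); c->a2 = getp(p, "a2");
  c->p_ip3r = getp(p, "p_ip3r");
  c->p_serca = getp(p, "p_serca"); c->k_serca = getp(p, "k_serca");
  c->p_caerl = getp(p, "p_caerl");
  c->p_ncx = getp(p, "p_ncx"); c->k_ncx_na = getp(p, "k_ncx_na");
  c->k_ncx_ca = getp(p, "k_ncx_ca"); c->eta_ncx = getp(p, "eta_ncx");
  c->ksat_ncx = getp(p, "ksat_ncx");
  c->p_glut = getp(p, "p_glut"); c->k_glut = getp(p, "k_glut");
  c->p_nka = getp(p, "p_nka"); c->k_nka_na = getp(p, "k_nka_na");
  c->k_nka_k = getp(p, "k_nka_k");
  c->g_nal = getp(p, "g_nal"); c->g_kl = getp(p, "g_kl");
  c->o_beta_glu = getp(p, "o_beta_glu"); c->k_r_glu = getp(p, "k_r_glu");
  c->k_p_glu = getp(p, "k_p_glu"); c->k_pi_glu = getp(p, "k_pi_glu");
  c->o_beta_da = getp(p, "o_beta_da"); c->k_r_da = getp(p, "k_r_da");
  c->k_p_da = getp(p, "k_p_da"); c->k_pi_da = getp(p, "k_pi_da");
  c->o_delta = getp(p, "o_delta"); c->kappa_delta = getp(p, "kappa_delta");
  c->k_delta = getp(p, "k_delta");
  c->o_3k = getp(p, "o_3k"); c->k_d_3k = getp(p, "k_d_3k");
  c->k_3_3k = getp(p, "k_3_3k"); c->omega_5p = getp(p, "omega_5p");
  c->g_glu_decay = getp(p, "g_glu_decay"); c->g_da_decay = getp(p, "g_da_decay");
  c->rho_glu = getp(p, "rho_glu"); c->rho_da = getp(p, "rho_da");
  c->d_ca = getp(p, "d_ca"); c->d_ip3 = getp(p, "d_ip3");
  c->d_cae = getp(p, "d_cae"); c->d_caer = getp(p, "d_caer");
  c->d_na = getp(p, "d_na");
  c->d_k = getp(p, "d_k"); c->d_glu = getp(p, "d_glu");
  c->d_da = getp(p, "d_da");
  c->include_er_currents = as<bool>(p["include_er_currents"]);
  c->ca_e0 = getp(p, "ca_e0"); c->na_i0 = getp(p, "na_i0");
  c->na_e0 = getp(p, "na_e0"); c->k_i0 = getp(p, "k_i0");
  c->k_e0 = getp(p, "k_e0"); c->v0 = getp(p, "v0");
  c->ca_er0 = getp(p, "ca_er0"); c->ca_i0 = getp(p, "ca_i0");
  c->ip3_0 = getp(p, "ip3_0");
  c->h_avg = getp(p, "h0");
  c->glu_scale = 1.0; c->da_scale = 1.0;
  if (p.containsElementNamed("glu_scale")) c->glu_scale = getp(p, "glu_scale");
  if (p.containsElementNamed("da_scale")) c->da_scale = getp(p, "da_scale");
  if (p.containsElementNamed("h_avg")) c->h_avg = getp(p, "h_avg");
  XPtr<ModelCtx> ptr(c, true);
  return ptr;
}

static inline double hill2c(double x, double k) {
  return x * x / (x * x + k * k);
}

static inline double plc_beta_c(double ag, double ca, double o, double kr,
                                double kp, double kpi) {
  if (o == 0.0 || ag <= 0.0) return 0.0;
  double keff = kr * (1.0 + (kp / kr) * ca / (ca + kpi));
  double a = std::pow(ag, 0.7);
  return o * a / (a + std::pow(keff, 0.7));
}

// dilute shot-noise average of PLC-beta occupancy (see R counterpart)
static inline double plc_beta_shot_c(double mean_conc, double rho, double ca,
                                     double o, double kr, double kp,
                                     double kpi) {
  if (o == 0.0 || mean_conc <= 0.0) return 0.0;
  double keff = kr * (1.0 + (kp / kr) * ca / (ca + kpi));
  return o * (mean_conc / rho) * (10.0 / 7.0) *
         std::log1p(std::pow(rho / keff, 0.7));
}

static inline double ncx_c(const ModelCtx* c, double ca_i, double ca_e,
                           double na_i, double na_e, double v) {
  double phi = v / c->rtf;
  double ef = std::exp(c->eta_ncx * phi);
  double er = std::exp((c->eta_ncx - 1.0) * phi);
  double na_i3 = na_i * na_i * na_i, na_e3 = na_e * na_e * na_e;
  double kna3 = c->k_ncx_na * c->k_ncx_na * c->k_ncx_na;
  double num = na_i3 * ca_e * ef - na_e3 * ca_i * er;
  double den = (kna3 + na_e3) * (c->k_ncx_ca + ca_e) *
               (1.0 + c->ksat_ncx * er);
  return c->p_ncx * num / den;
}

// [[Rcpp::export]]
NumericVector rhs_compiled(double t, NumericVector y, SEXP ctxp) {
  XPtr<ModelCtx> ctx(ctxp);
  const ModelCtx* c = ctx.get();
  const int n = c->n;
  NumericVector dy(12 * n);
  const double kca = 1e9 / (2.0 * c->faraday);
  const double kion = 1e6 / c->faraday;
  const double kv = 1e3 / c->cm;
  for (int j = 0; j < n; ++j) {
    const double* s = &y[12 * j];
    double ca_i = s[0], ca_e = s[1], ca_er = s[2], ip3 = s[3], h = s[4];
    double na_i = s[5], na_e = s[6], k_i = s[7], k_e = s[8], v = s[9];
    double glu = s[10], da = s[11];
    double m = ip3 / (ip3 + c->d1), nn = ca_i / (ca_i + c->d5);
    double gate = std::pow(m * nn * h, 3.0);
    double j_ip3r = c->p_ip3r * gate * (ca_er - ca_i);
    double j_serca = c->p_serca * hill2c(ca_i, c->k_serca);
    double j_caerl = c->p_caerl * (ca_er - ca_i);
    double j_ncx = ncx_c(c, ca_i, ca_e, na_i, na_e, v);
    double j_glut = c->p_glut * glu / (glu + c->k_glut);
    double j_nka = c->p_nka *
      (std::pow(na_i, 1.5) / (std::pow(na_i, 1.5) + std::pow(c->k_nka_na, 1.5))) *
      (k_e / (k_e + c->k_nka_k));
    double j_nal = c->g_nal * (v - c->rtf * std::log(na_e / na_i));
    double j_kl = c->g_kl * (v - c->rtf * std::log(k_e / k_i));
    double er_net = j_ip3r - j_serca + j_caerl;
    double s_bg = plc_beta_c(glu, ca_i, c->o_beta_glu, c->k_r_glu,
                             c->k_p_glu, c->k_pi_glu);
    double s_bd = plc_beta_c(da, ca_i, c->o_beta_da, c->k_r_da,
                             c->k_p_da, c->k_pi_da);
    double s_d = c->o_delta / (1.0 + ip3 / c->kappa_delta) *
                 hill2c(ca_i, c->k_delta);
    double ca4 = ca_i * ca_i * ca_i * ca_i;
    double kd4 = std::pow(c->k_d_3k, 4.0);
    double d3k = c->o_3k * ca4 / (ca4 + kd4) * ip3 / (ip3 + c->k_3_3k);
    double d5p = c->omega_5p * ip3;
    double q2 = c->d2 * (ip3 + c->d1) / (ip3 + c->d3);
    double av = c->av[j], rer = c->rer[j];
    double na_flux = kion * av * (3 * j_glut - 3 * j_nka - 3 * j_ncx - j_nal);
    double k_flux = kion * av * (-j_glut + 2 * j_nka - j_kl);
    double er_v = c->include_er_currents ?
      (-2 * j_ip3r + 2 * j_serca - 2 * j_caerl) : 0.0;
    double* d = &dy[12 * j];
    d[0] = kca * av * j_ncx + kca * av * rer * er_net;
    d[1] = -kca * av * j_ncx;
    d[2] = -kca * av * er_net;
    d[3] = s_bg + s_bd + s_d - d3k - d5p;
    d[4] = c->a2 * (q2 * (1.0 - h) - ca_i * h);
    d[5] = na_flux;
    d[6] = -na_flux;
    d[7] = k_flux;
    d[8] = -k_flux;
    d[9] = -kv * (er_v + j_ncx - 2 * j_glut + j_nka + j_nal + j_kl);
    d[10] = -c->g_glu_decay * glu;
    d[11] = -c->g_da_decay * da;
  }
  // diffusive coupling (per-species coefficients)
  const double Dv[12] = {c->d_ca, c->d_cae, c->d_caer, c->d_ip3, 0.0,
                         c->d_na, c->d_na, c->d_k, c->d_k, 0.0,
                         c->d_glu, c->d_da};
  for (size_t e = 0; e < c->edges.size(); ++e) {
    const Edge& ed = c->edges[e];
    for (int vi = 0; vi < 12; ++vi) {
      if (Dv[vi] == 0.0) continue;
      dy[12 * ed.j + vi] += Dv[vi] * ed.g *
        (y[12 * ed.k + vi] - y[12 * ed.j + vi]);
    }
  }
  return dy;
}

// Simplified (c, i) chain model. State is (c, i, glu, da) per compartment;
// c and i are numerically in uM (dimensionless via unit concentration);
// fast variables are pinned to rest, h to its average, ER calcium to its
// resting value. If use_mean_drive, the transmitter states are ignored and
// the constant levels glu0/da0 (uM) are used; otherwise the glu/da states
// decay and receive release jumps through solver events.
// [[Rcpp::export]]
NumericVector rhs_simplified_chain(double t, NumericVector y, SEXP ctxp,
                                   bool use_mean_drive,
                                   NumericVector glu0, NumericVector da0,
                                   double d_ca, double d_ip3) {
  XPtr<ModelCtx> ctx(ctxp);
  const ModelCtx* c = ctx.get();
  const int n = c->n;
  NumericVector dy(4 * n);
  const double kca = 1e9 / (2.0 * c->faraday);
  for (int j = 0; j < n; ++j) {
    double ca_i = y[4 * j], ip3 = y[4 * j + 1];
    double glu_j = use_mean_drive ? glu0[j] : y[4 * j + 2];
    double da_j = use_mean_drive ? da0[j] : y[4 * j + 3];
    double m = ip3 / (ip3 + c->d1), nn = ca_i / (ca_i + c->d5);
    double gate = std::pow(m * nn * c->h_avg, 3.0);
    double j_ip3r = c->p_ip3r * gate * (c->ca_er0 - ca_i);
    double j_serca = c->p_serca * hill2c(ca_i, c->k_serca);
    double j_caerl = c->p_caerl * (c->ca_er0 - ca_i);
    double j_ncx = ncx_c(c, ca_i, c->ca_e0, c->na_i0, c->na_e0, c->v0);
    double s_bg = use_mean_drive ?
      plc_beta_shot_c(glu_j, c->rho_glu, ca_i, c->o_beta_glu, c->k_r_glu,
                      c->k_p_glu, c->k_pi_glu) :
      plc_beta_c(glu_j, ca_i, c->o_beta_glu, c->k_r_glu,
                 c->k_p_glu, c->k_pi_glu);
    double s_bd = use_mean_drive ?
      plc_beta_shot_c(da_j, c->rho_da, ca_i, c->o_beta_da, c->k_r_da,
                      c->k_p_da, c->k_pi_da) :
      plc_beta_c(da_j, ca_i, c->o_beta_da, c->k_r_da,
                 c->k_p_da, c->k_pi_da);
    double s_d = c->o_delta / (1.0 + ip3 / c->kappa_delta) *
                 hill2c(ca_i, c->k_delta);
    double ca4 = ca_i * ca_i * ca_i * ca_i;
    double kd4 = std::pow(c->k_d_3k, 4.0);
    double d3k = c->o_3k * ca4 / (ca4 + kd4) * ip3 / (ip3 + c->k_3_3k);
    double d5p = c->omega_5p * ip3;
    double av = c->av[j], rer = c->rer[j];
    dy[4 * j] = kca * av * j_ncx +
                kca * av * rer * (j_ip3r - j_serca + j_caerl);
    dy[4 * j + 1] = s_bg + s_bd + s_d - d3k - d5p;
    if (!use_mean_drive) {
      dy[4 * j + 2] = -c->g_glu_decay * glu_j;
      dy[4 * j + 3] = -c->g_da_decay * da_j;
    }
  }
  for (size_t e = 0; e < c->edges.size(); ++e) {
    const Edge& ed = c->edges[e];
    dy[4 * ed.j] += d_ca * ed.g * (y[4 * ed.k] - y[4 * ed.j]);
    dy[4 * ed.j + 1] += d_ip3 * ed.g * (y[4 * ed.k + 1] - y[4 * ed.j + 1]);
    if (!use_mean_drive) {
      dy[4 * ed.j + 2] += c->d_glu * ed.g * (y[4 * ed.k + 2] - y[4 * ed.j + 2]);
      dy[4 * ed.j + 3] += c->d_da * ed.g * (y[4 * ed.k + 3] - y[4 * ed.j + 3]);
    }
  }
  return dy;
}
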