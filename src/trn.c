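/* Compiled right-hand sides of the TRN conductance model, its
 * three-variable reduction and the frozen-z fast subsystem, for use with
 * deSolve. Mirrors the reference R implementations (.fullDeriv,
 * .reducedDeriv, .fastDeriv) exactly; the R versions remain the
 * documented API and the two paths are cross-checked in the tests.
 *
 * Parameter vector (shared by all three systems):
 *  0 C, 1 A, 2 gL, 3 gKL, 4 gNa, 5 gK, 6 gT,
 *  7 EL, 8 EKL, 9 ENa, 10 EK, 11 ET,
 *  12 VthNa, 13 VthK, 14 VthT,
 *  15 phi_m, 16 phi_h, 17 phi_n, 18 phi_p, 19 phi_q,
 *  20 k, 21 Ieff (stimulus density, uA/cm^2), 22 z (fast subsystem only),
 *  23 steepness mode for the collapsed intermediate group (y row):
 *     0 = theta_inf' at the relaxing variable y, 1 = at the driving
 *     voltage x; the z row always uses q_inf'(z) (z = v_q is exact)
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[24];
#define P_C      parms[0]
#define P_gL     parms[2]
#define P_gKL    parms[3]
#define P_gNa    parms[4]
#define P_gK     parms[5]
#define P_gT     parms[6]
#define P_EL     parms[7]
#define P_EKL    parms[8]
#define P_ENa    parms[9]
#define P_EK     parms[10]
#define P_ET     parms[11]
#define P_VthNa  parms[12]
#define P_VthK   parms[13]
#define P_VthT   parms[14]
#define P_phim   parms[15]
#define P_phih   parms[16]
#define P_phin   parms[17]
#define P_phip   parms[18]
#define P_phiq   parms[19]
#define P_k      parms[20]
#define P_Ieff   parms[21]
#define P_zfroz  parms[22]
#define P_smode  parms[23]

void trn_initmod(void (*odeparms)(int *, double *))
{
    int n = 24;
    odeparms(&n, parms);
}

/* u/(exp(u/c)-1) with the analytic limit at the removable singularity */
static double sgrowth(double u, double c)
{
    double s = u / c;
    if (fabs(s) < 1e-7) return c - u / 2.0;
    return u / expm1(s);
}

/* d/du of sgrowth */
static double sgrowth_d(double u, double c)
{
    double s = u / c;
    if (fabs(s) < 1e-5) return -0.5 + s / 6.0;
    double E = expm1(s);
    return (E - s * exp(s)) / (E * E);
}

static double logistic(double s) { return 1.0 / (1.0 + exp(-s)); }

/* alpha/beta rates and voltage derivatives of the spiking gates */
static void rates_m(double V, double *a, double *b, double *da, double *db)
{
    double u = 13.0 - V + P_VthNa, w = V - 40.0 - P_VthNa;
    *a = 0.32 * sgrowth(u, 4.0);
    *b = 0.28 * sgrowth(w, 5.0);
    if (da) *da = -0.32 * sgrowth_d(u, 4.0);
    if (db) *db = 0.28 * sgrowth_d(w, 5.0);
}

static void rates_h(double V, double *a, double *b, double *da, double *db)
{
    double s = logistic((V - 40.0 - P_VthNa) / 5.0);
    *a = 0.128 * exp((17.0 - V + P_VthNa) / 18.0);
    *b = 4.0 * s;
    if (da) *da = -(*a) / 18.0;
    if (db) *db = 4.0 * s * (1.0 - s) / 5.0;
}

static void rates_n(double V, double *a, double *b, double *da, double *db)
{
    double u = 15.0 - V + P_VthK;
    *a = 0.032 * sgrowth(u, 5.0);
    *b = 0.5 * exp((10.0 - V + P_VthK) / 10.0);
    if (da) *da = -0.032 * sgrowth_d(u, 5.0);
    if (db) *db = -(*b) / 10.0;
}

static double inf_ab(double a, double b) { return a / (a + b); }
static double infd_ab(double a, double b, double da, double db)
{
    double s = a + b;
    return (da * b - a * db) / (s * s);
}

static double p_inf(double V) { return logistic((52.0 + V - P_VthT) / 7.4); }
static double q_inf(double V) { return logistic(-(80.0 + V - P_VthT) / 5.0); }
static double p_infd(double V) { double s = p_inf(V); return s * (1 - s) / 7.4; }
static double q_infd(double V) { double s = q_inf(V); return -s * (1 - s) / 5.0; }

static double tau_p(double V)
{
    return 3.0 + 1.0 / (exp((V + 27.0 - P_VthT) / 10.0) +
                        exp(-(V + 102.0 - P_VthT) / 15.0));
}

static double tau_q(double V)
{
    return 85.0 + 1.0 / (exp((V + 48.0 - P_VthT) / 4.0) +
                         exp(-(V + 407.0 - P_VthT) / 50.0));
}

static double clamp01(double x)
{
    if (x < 0.0) return 0.0;
    if (x > 1.0) return 1.0;
    return x;
}

void trn_full_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double V = y[0];
    double m = clamp01(y[1]), h = clamp01(y[2]), n = clamp01(y[3]);
    double p = clamp01(y[4]), q = clamp01(y[5]);
    double am, bm, ah, bh, an, bn;
    rates_m(V, &am, &bm, NULL, NULL);
    rates_h(V, &ah, &bh, NULL, NULL);
    rates_n(V, &an, &bn, NULL, NULL);
    double Iion = P_gNa * m * m * m * h * (V - P_ENa) +
        P_gK * n * n * n * n * (V - P_EK) +
        P_gT * p * p * q * (V - P_ET) +
        P_gL * (V - P_EL) + P_gKL * (V - P_EKL);
    ydot[0] = (P_Ieff - Iion) / P_C;
    ydot[1] = P_phim * (am * (1.0 - m) - bm * m);
    ydot[2] = P_phih * (ah * (1.0 - h) - bh * h);
    ydot[3] = P_phin * (an * (1.0 - n) - bn * n);
    ydot[4] = P_phip * (p_inf(V) - p) / tau_p(V);
    ydot[5] = P_phiq * (q_inf(V) - q) / tau_q(V);
}

#define RHO_V_FLOOR 1e-6

/* d(x,y,z)/dt of the reduced system; z frozen when frozen_z != 0 */
static void reduced_core(double x, double yv, double z, double *ydot,
                         int frozen_z)
{
    double am, bm, dam, dbm, ah, bh, dah, dbh, an, bn, dan, dbn;

    /* steady states at x (m) and y (h, n, p) with their derivatives */
    rates_m(x, &am, &bm, &dam, &dbm);
    double minf_x = inf_ab(am, bm), minfd_x = infd_ab(am, bm, dam, dbm);
    double tau_m_x = 1.0 / (am + bm);

    rates_h(yv, &ah, &bh, &dah, &dbh);
    double hinf_y = inf_ab(ah, bh), hinfd_y = infd_ab(ah, bh, dah, dbh);
    rates_n(yv, &an, &bn, &dan, &dbn);
    double ninf_y = inf_ab(an, bn), ninfd_y = infd_ab(an, bn, dan, dbn);
    double pinf_y = p_inf(yv), pinfd_y = p_infd(yv);
    double qinf_z = q_inf(z);

    /* partial derivatives of F at (V=x, v_m=x, v_h=v_n=v_p=y, v_q=z) */
    double m3 = minf_x * minf_x * minf_x;
    double n4 = ninf_y * ninf_y * ninf_y * ninf_y;
    double FV = P_gNa * m3 * hinf_y + P_gK * n4 +
        P_gT * pinf_y * pinf_y * qinf_z + P_gL + P_gKL;
    double Fvm = 3.0 * P_gNa * minf_x * minf_x * minfd_x * hinf_y *
        (x - P_ENa);
    double Fvh = P_gNa * m3 * hinfd_y * (x - P_ENa);
    double Fvn = 4.0 * P_gK * ninf_y * ninf_y * ninf_y * ninfd_y *
        (x - P_EK);
    double Fvp = 2.0 * P_gT * pinf_y * pinfd_y * qinf_z * (x - P_ET);

    /* grouping weights */
    double k = P_k;
    double den = Fvh + Fvn, rho_h, rho_n;
    if (!R_FINITE(den) || fabs(den) < 1e-300) {
        rho_h = rho_n = (1.0 - k) / 2.0;
    } else {
        rho_h = (1.0 - k) * Fvh / den;
        rho_n = (1.0 - k) * Fvn / den;
    }
    double a = P_C * P_phim / tau_m_x;
    double BD = FV + Fvm, rho_V;
    if (fabs(BD) < 1e-12) {
        rho_V = a / (a + FV);
    } else {
        double disc = (a + FV) * (a + FV) - 4.0 * a * BD;
        if (disc < 0) {
            rho_V = a / (a + FV);
        } else {
            double r1 = (-(a + FV) + sqrt(disc)) / (-2.0 * BD);
            double r2 = (-(a + FV) - sqrt(disc)) / (-2.0 * BD);
            rho_V = (r1 >= 0.0 && r1 <= 1.0) ? r1 : r2;
        }
        if (!R_FINITE(rho_V) || rho_V < 0.0 || rho_V > 1.0) {
            rho_V = a / (a + FV);
            if (rho_V < 0.0) rho_V = 0.0;
            if (rho_V > 1.0) rho_V = 1.0;
        }
    }
    if (rho_V < RHO_V_FLOOR) rho_V = RHO_V_FLOOR;

    /* voltage equation */
    double F = P_gNa * m3 * hinf_y * (x - P_ENa) +
        P_gK * n4 * (x - P_EK) +
        P_gT * pinf_y * pinf_y * qinf_z * (x - P_ET) +
        P_gL * (x - P_EL) + P_gKL * (x - P_EKL);
    ydot[0] = (P_Ieff - F) / (P_C * rho_V);

    /* intermediate group: weighted equivalent-potential relaxation */
    double ah2, bh2, dah2, dbh2, an2, bn2, dan2, dbn2;
    rates_h(x, &ah2, &bh2, &dah2, &dbh2);
    rates_n(x, &an2, &bn2, &dan2, &dbn2);
    double hinf_x = inf_ab(ah2, bh2), tau_h_x = 1.0 / (ah2 + bh2);
    double ninf_x = inf_ab(an2, bn2), tau_n_x = 1.0 / (an2 + bn2);
    double pinf_x = p_inf(x), tau_p_x = tau_p(x);
    int at_x = P_smode > 0.5;
    double hd = at_x ? infd_ab(ah2, bh2, dah2, dbh2) : hinfd_y;
    double nd = at_x ? infd_ab(an2, bn2, dan2, dbn2) : ninfd_y;
    double pd = at_x ? p_infd(x) : pinfd_y;
    ydot[1] = rho_h * P_phih * (hinf_x - hinf_y) / (tau_h_x * hd) +
        rho_n * P_phin * (ninf_x - ninf_y) / (tau_n_x * nd) +
        k * P_phip * (pinf_x - pinf_y) / (tau_p_x * pd);

    /* slow variable (fixed when z is treated as a parameter); z = v_q
     * exactly, so its chain rule always uses q_inf'(z) */
    ydot[2] = frozen_z ? 0.0 :
        P_phiq * (q_inf(x) - qinf_z) / (tau_q(x) * q_infd(z));
}

void trn_reduced_derivs(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    reduced_core(y[0], y[1], y[2], ydot, 0);
}

void trn_fast_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double d[3];
    reduced_core(y[0], y[1], P_zfroz, d, 1);
    ydot[0] = d[0];
    ydot[1] = d[1];
}

static const R_CMethodDef CEntries[] = {
    {"trn_initmod",        (DL_FUNC) &trn_initmod,        1},
    {"trn_full_derivs",    (DL_FUNC) &trn_full_derivs,    6},
    {"trn_reduced_derivs", (DL_FUNC) &trn_reduced_derivs, 6},
    {"trn_fast_derivs",    (DL_FUNC) &trn_fast_derivs,    6},
    {NULL, NULL, 0}
};

void R_init_trnreduce(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
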