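/* MinCell: minimal paced ventricular myocyte model with dynamic hERG-drug
 * binding.  Hodgkin-Huxley style gates; the L-type calcium current keeps a
 * steady-state window (overlapping activation/inactivation with a slow,
 * partially recovering f gate) so that early afterdepolarizations can arise
 * when repolarization is delayed.
 *
 * State layout (11):
 *   0 V (mV), 1 m, 2 h, 3 hL, 4 r, 5 xs, 6 xr, 7 d, 8 f,
 *   9 Cai (nM), 10 b (hERG drug-bound fraction)
 *
 * Parameter layout (20), shared with R/mincell.R (keep in sync):
 *   0 gNa 1 gNaL 2 gto 3 gKs 4 gKr 5 gK1 6 gCaL   (mS/uF, block-scaled)
 *   7 ENa 8 EK 9 ECa                              (mV)
 *  10 sbIKr 11 Ku (1/ms) 12 Vhalf (mV) 13 kT (mV) 14 extraKr (fraction 0..1)
 *  15 kCaL (nM uF / uA / ms) 16 tauCa (ms) 17 Ca0 (nM)
 *  18 stim_amp (uA/uF) 19 stim_on (0/1)
 *  20 gpump (uA/uF) 21 gbg (mS/uF)
 *
 * Ipump (outward, Na/K-pump-like) and Ibg (inward background) lie outside
 * the qNet current set, as the pump/exchanger/background currents of the
 * reference model family do.
 *
 * Output layout (7): INa INaL Ito IKs IKr IK1 ICaL (uA/uF)
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_STATE 11
#define N_PAR   22
#define N_OUT   7

static double pars[N_PAR];

static double sig(double v, double v0, double k)
{
    return 1.0 / (1.0 + exp(-(v - v0) / k));
}

static void mincell_core(double t, const double *y, const double *p,
                         double *ydot, double *cur)
{
    double V = y[0], m = y[1], h = y[2], hL = y[3], r = y[4];
    double xs = y[5], xr = y[6], d = y[7], f = y[8], Cai = y[9], b = y[10];

    double INa  = p[0] * m * m * m * h * (V - p[7]);
    double INaL = p[1] * sig(V, -42.0, 5.5) * hL * (V - p[7]);
    double Ito  = p[2] * sig(V, 0.0, 13.0) * r * (V - p[8]);
    double IKs  = p[3] * xs * xs * (V - p[8]);
    double rkr  = 1.0 / (1.0 + exp((V - 15.0) / 22.0));
    double IKr  = p[4] * (1.0 - p[14]) * (1.0 - b) * xr * rkr * (V - p[8]);
    double IK1  = p[5] / (1.0 + exp((V + 80.0) / 8.0)) * (V - p[8]);
    double ICaL = p[6] * d * f * (V - p[9]);
    double Ipump = p[20] / (1.0 + exp(-(V + 70.0) / 8.0));
    double Ibg  = p[21] * (V - p[7]);
    double Istim = (p[19] != 0.0) ? p[18] : 0.0;

    ydot[0] = -(INa + INaL + Ito + IKs + IKr + IK1 + ICaL
                + Ipump + Ibg + Istim);
    ydot[1] = (sig(V, -40.0, 7.0) - m) / 0.2;
    {
        double tauh = 0.3 + 12.0 / (1.0 + exp((V + 50.0) / 6.0));
        ydot[2] = (1.0 / (1.0 + exp((V + 76.0) / 5.5)) - h) / tauh;
    }
    ydot[3] = (1.0 / (1.0 + exp((V + 75.0) / 7.0)) - hL) / 200.0;
    ydot[4] = (1.0 / (1.0 + exp((V + 40.0) / 5.0)) - r) / 15.0;
    ydot[5] = (sig(V, -11.0, 14.0) - xs) / 400.0;
    {
        double tauxr = 100.0 + 200.0 / (1.0 + exp((V + 30.0) / 15.0));
        ydot[6] = (sig(V, -21.0, 7.0) - xr) / tauxr;
    }
    {
        double taud = 1.0 + 4.0 * exp(-((V + 18.0) / 20.0) * ((V + 18.0) / 20.0));
        ydot[7] = (sig(V, -18.0, 6.0) - d) / taud;
    }
    {
        double finf = 1.0 / (1.0 + exp((V + 28.0) / 7.0))
                    + 0.35 / (1.0 + exp((50.0 - V) / 20.0));
        double tauf = 25.0 + 120.0 * exp(-((V + 30.0) / 25.0) * ((V + 30.0) / 25.0));
        ydot[8] = (finf - f) / tauf;
    }
    ydot[9] = -p[15] * ICaL - (Cai - p[17]) / p[16];
    {
        double T  = 1.0 / (1.0 + exp(-(V - p[12]) / p[13]));
        double op = xr * rkr;
        ydot[10] = p[11] * p[10] * op * (1.0 - b) - p[11] * T * b;
    }

    if (cur) {
        cur[0] = INa;  cur[1] = INaL; cur[2] = Ito; cur[3] = IKs;
        cur[4] = IKr;  cur[5] = IK1;  cur[6] = ICaL;
    }
}

/* deSolve interface */
void mincell_init(void (*odeparms)(int *, double *))
{
    int n = N_PAR;
    odeparms(&n, pars);
}

void mincell_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    if (ip[0] < N_OUT) error("mincell_derivs: nout too small");
    mincell_core(*t, y, pars, ydot, yout);
}

/* direct single evaluation, used by the R-level rhs wrapper */
SEXP C_mincell_rhs(SEXP st, SEXP sy, SEXP sp)
{
    if (LENGTH(sy) != N_STATE) error("state must have length %d", N_STATE);
    if (LENGTH(sp) != N_PAR) error("parameter vector must have length %d", N_PAR);
    SEXP ydot = PROTECT(allocVector(REALSXP, N_STATE));
    SEXP cur  = PROTECT(allocVector(REALSXP, N_OUT));
    mincell_core(REAL(st)[0], REAL(sy), REAL(sp), REAL(ydot), REAL(cur));
    SEXP ans = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(ans, 0, ydot);
    SET_VECTOR_ELT(ans, 1, cur);
    UNPROTECT(3);
    return ans;
}

static const R_CallMethodDef callMethods[] = {
    {"C_mincell_rhs", (DL_FUNC) &C_mincell_rhs, 3},
    {NULL, NULL, 0}
};

void R_init_proarisk(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);  /* deSolve looks up entry points by name */
}
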