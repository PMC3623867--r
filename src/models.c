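/* Compiled right-hand sides for the built-in benchmark systems, in the
 * deSolve "compiled model" convention (an init function receiving the
 * parameter vector, and a derivative function), plus a fast iterator for
 * the discrete nonlinear map benchmark.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* ---- two-switch transcriptional oscillator -------------------------------
 * states: A (RNA activator), B (RNA inhibitor), C (ON fraction of switch
 * Sw21), D (ON fraction of switch Sw12); parameters: K1, n1 (activation
 * threshold and Hill coefficient of Sw21), K2, n2 (inhibition threshold and
 * Hill coefficient of Sw12), v (RNA production rate of an ON switch).
 * Degradation/relaxation rates are scaled to 1 (dimensionless time).
 */
static double osc_p[5];

void scro_init_osc(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, osc_p);
}

void scro_deriv_osc(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double K1 = osc_p[0], n1 = osc_p[1], K2 = osc_p[2], n2 = osc_p[3],
           v = osc_p[4];
    /* guard against tiny negative excursions of the solver before pow() */
    double A = y[0] > 0 ? y[0] : 0.0;
    double B = y[1] > 0 ? y[1] : 0.0;
    double an = pow(A, n1), kn = pow(K1, n1);
    double bn = pow(B, n2), k2n = pow(K2, n2);
    double act = (an + kn) > 0 ? an / (an + kn) : 0.0;
    double rep = (bn + k2n) > 0 ? k2n / (bn + k2n) : 0.0;

    ydot[0] = v * y[3] - y[0];
    ydot[1] = v * y[2] - y[1];
    ydot[2] = act - y[2];
    ydot[3] = rep - y[3];
}

/* ---- extracellular protease production (DegS-DegU) -----------------------
 * states: A AprE, B DegU, C DegU~P, D (DegU~P)2 dimer, E mAprE, F mDegU.
 * parameters k1..k17 (0-based k[0..16]):
 *  k1  translation mDegU -> DegU         k10 phosphorylation DegU -> DegU~P
 *  k2  DegU basal degradation            k11 dimer dissociation
 *  k3  DegU~P degradation                k12 mAprE degradation
 *  k4  AprE degradation                  k13 constitutive DegU supply
 *  k5  dimer degradation                 k14 activation constant (dimer)
 *  k6  mDegU degradation                 k15 activated mAprE transcription
 *  k7  translation mAprE -> AprE         k16 dephosphorylation (path 1)
 *  k8  dimer association                 k17 dephosphorylation (path 2)
 *  k9  mDegU transcription
 */
static double prot_p[17];

void scro_init_prot(void (*odeparms)(int *, double *))
{
    int n = 17;
    odeparms(&n, prot_p);
}

void scro_deriv_prot(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double *k = prot_p;
    double C = y[2] > 0 ? y[2] : 0.0;
    double D = y[3] > 0 ? y[3] : 0.0;
    double deph = (k[15] + k[16]) * C;

    ydot[0] = k[6] * y[4] - k[3] * y[0];
    ydot[1] = k[12] + k[0] * y[5] + deph - (k[9] + k[1]) * y[1];
    ydot[2] = k[9] * y[1] - deph - k[2] * C - 2.0 * k[7] * C * C
              + 2.0 * k[10] * D;
    ydot[3] = k[7] * C * C - (k[10] + k[4]) * D;
    ydot[4] = k[14] * D / (k[13] + D) - k[11] * y[4];
    ydot[5] = k[8] - k[5] * y[5];
}

/* ---- discrete nonlinear map ----------------------------------------------
 * x1' = a x1 + x2/(1+x2^2) + e1;  x2' = b x2 (1-x2) + e2;  x3' = x1 x2 + e3.
 * noise: (nsteps x 3) matrix of pre-drawn process-noise terms, or NULL.
 * Returns an (nsteps+1) x 3 matrix including the initial state; errors with
 * the 1-based step index if the orbit leaves the finite range.
 */
SEXP scro_sim_map(SEXP ab_, SEXP x0_, SEXP nsteps_, SEXP noise_)
{
    int n = asInteger(nsteps_);
    double a = REAL(ab_)[0], b = REAL(ab_)[1];
    SEXP out = PROTECT(allocMatrix(REALSXP, n + 1, 3));
    double *o = REAL(out);
    double *e = (noise_ == R_NilValue) ? NULL : REAL(noise_);
    double x1 = REAL(x0_)[0], x2 = REAL(x0_)[1], x3 = REAL(x0_)[2];
    int nr = n + 1;

    o[0] = x1; o[nr] = x2; o[2 * nr] = x3;
    for (int i = 0; i < n; i++) {
        double y1 = a * x1 + x2 / (1.0 + x2 * x2);
        double y2 = b * x2 * (1.0 - x2);
        double y3 = x1 * x2;
        if (e) {
            y1 += e[i];
            y2 += e[i + n];
            y3 += e[i + 2 * n];
        }
        if (!R_FINITE(y1) || !R_FINITE(y2) || !R_FINITE(y3) ||
            fabs(y1) > 1e8 || fabs(y2) > 1e8 || fabs(y3) > 1e8) {
            UNPROTECT(1);
            error("discrete map diverged at step %d", i + 1);
        }
        x1 = y1; x2 = y2; x3 = y3;
        o[i + 1] = x1; o[i + 1 + nr] = x2; o[i + 1 + 2 * nr] = x3;
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"scro_sim_map", (DL_FUNC) &scro_sim_map, 4},
    {NULL, NULL, 0}
};

void R_init_scro(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    /* deSolve looks the derivative routines up by name */
    R_useDynamicSymbols(dll, TRUE);
}
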