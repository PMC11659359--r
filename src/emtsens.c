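/* Compiled right-hand side for the E-cadherin/Slug ODE, in the grouped form
 *
 *   dE/dt = a1 / (1 + (S/icS)^n1) + hc - b1 * E
 *   dS/dt = a2 - k1 * (E/icE)^n3 / (1 + (E/icE)^n3) + ht - b2 * S
 *
 * where hc and ht are the (trajectory-constant) contact and TGF-beta Hill
 * inputs, precomputed in R.  The dimensional model maps onto this directly;
 * the nondimensional model is the special case icS = icE = 1.  Parameter
 * vector layout (see grouped_form() in R/model.R):
 *   p = (a1, icS, n1, hc, b1, a2, k1, icE, n3, ht, b2)
 */
#include <R.h>
#include <Rmath.h>
#include <R_ext/Rdynload.h>

static double p[11];

void emt_init(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, p);
}

void emt_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double E = y[0], S = y[1];
    double hs = R_pow(S / p[1], p[2]);   /* (S/icS)^n1 */
    double he = R_pow(E / p[7], p[8]);   /* (E/icE)^n3 */

    ydot[0] = p[0] / (1.0 + hs) + p[3] - p[4] * E;
    ydot[1] = p[5] - p[6] * he / (1.0 + he) + p[9] - p[10] * S;
}

/* Analytic Jacobian for the stiff solver.  Both off-diagonal Hill
 * derivatives are negative: Slug represses E-cadherin production and
 * membrane E-cadherin suppresses Slug. */
void emt_jac(int *neq, double *t, double *y, int *ml, int *mu,
             double *pd, int *nrowpd, double *yout, int *ip)
{
    double E = y[0], S = y[1];
    double sr = S / p[1], er = E / p[7];
    double hs = R_pow(sr, p[2]);
    double he = R_pow(er, p[8]);
    double dhs = (S > 0.0) ? p[2] * R_pow(sr, p[2] - 1.0) / p[1] : 0.0;
    double dhe = (E > 0.0) ? p[8] * R_pow(er, p[8] - 1.0) / p[7] : 0.0;

    pd[0] = -p[4];                                        /* d(dE)/dE */
    pd[1] = -p[6] * dhe / ((1.0 + he) * (1.0 + he));      /* d(dS)/dE */
    pd[*nrowpd] = -p[0] * dhs / ((1.0 + hs) * (1.0 + hs)); /* d(dE)/dS */
    pd[*nrowpd + 1] = -p[10];                             /* d(dS)/dS */
}

static const R_CMethodDef CEntries[] = {
    {"emt_init",   (DL_FUNC) &emt_init,   1},
    {"emt_derivs", (DL_FUNC) &emt_derivs, 6},
    {"emt_jac",    (DL_FUNC) &emt_jac,    9},
    {NULL, NULL, 0}
};

void R_init_emtsens(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
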