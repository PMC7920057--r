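/* Compiled derivative functions for the two tumor-dynamics models,
 * in the deSolve compiled-code convention. Treatment gating is resolved
 * in R before each solve and passed through the parameter vector, so each
 * segment integrates a smooth ODE.
 *
 * LV parms:  rS_eff, delta_eff, rR, K, C
 * SW parms:  rS_eff, delta_eff, alpha_eff, beta_eff, rR, K
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double p_lv[5];

void lv_init(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, p_lv);
}

void lv_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double S = y[0], R = y[1];
    double crowd = 1.0 - (S + R) / p_lv[3];
    ydot[0] = p_lv[0] * crowd * S - p_lv[1] * S;
    ydot[1] = p_lv[2] * (1.0 - (p_lv[4] * S + R) / p_lv[3]) * R;
}

static double p_sw[6];

void sw_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, p_sw);
}

void sw_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double S = y[0], R = y[1];
    double crowd = 1.0 - (S + R) / p_sw[5];
    ydot[0] = p_sw[0] * crowd * S - p_sw[1] * S - p_sw[2] * S + p_sw[3] * R;
    ydot[1] = p_sw[4] * crowd * R + p_sw[2] * S - p_sw[3] * R;
}

void R_init_adaptherapy(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
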