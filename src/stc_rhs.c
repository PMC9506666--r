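/* Right-hand side of the synaptic tagging and capture model, in the
 * deSolve compiled-function interface. The stimulus Y and the drug
 * multiplier on alpha_Ud are piecewise constant, so the R integrator
 * passes them in the parameter vector and integrates segment by segment
 * between pulse/drug edges.
 *
 * State layout (length 3 + 5 N):
 *   y[0] U_d, y[1] M_d, y[2] P_d,
 *   then per-spine blocks U_s, T_p, P_s, Z, W of length N each.
 *
 * Parameter vector layout (length 51): see PAR_* below; Y occupies the
 * last 20 slots (padded).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 51

enum {
  PAR_N = 0,
  PAR_K_US, PAR_BETA_US,
  PAR_K_UD, PAR_ALPHA_EFF, PAR_BETA_UD, PAR_KK_UD, PAR_H_UD,
  PAR_TAU_MD, PAR_TAU_PD, PAR_MU_MD, PAR_MU_PD,
  PAR_K_PD, PAR_KK_PD, PAR_H_PD,
  PAR_K_PS, PAR_KK_PS, PAR_H_PS, PAR_BETA_PS,
  PAR_K_TP, PAR_KK_TP, PAR_H_TP, PAR_TAU_TP, PAR_MU_TP,
  PAR_K_Z, PAR_KK_Z, PAR_H_Z,
  PAR_K_W, PAR_KK_W, PAR_H_W, PAR_TAU_W,
  PAR_Y0  /* first of 20 Y slots */
};

static double parms[NPAR];

void stc_init(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, parms);
}

/* Hill activation; inputs clamped at 0 against solver overshoot */
static double hillf(double x, double K, double h)
{
  double xh, Kh;
  if (x <= 0.0) return 0.0;
  xh = pow(x, h);
  Kh = pow(K, h);
  return xh / (xh + Kh);
}

void stc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
  const int N = (int) parms[PAR_N];
  const double U_d = y[0], M_d = y[1], P_d = y[2];
  const double *U_s = y + 3, *T_p = y + 3 + N, *P_s = y + 3 + 2 * N,
               *Z = y + 3 + 3 * N, *W = y + 3 + 4 * N;
  double *dU_s = ydot + 3, *dT_p = ydot + 3 + N, *dP_s = ydot + 3 + 2 * N,
         *dZ = ydot + 3 + 3 * N, *dW = ydot + 3 + 4 * N;
  double drive = 0.0, cap_sum = 0.0, eff_sum = 0.0, synth;
  int n;

  if (*neq != 3 + 5 * N)
    error("stc_derivs: state length %d does not match N = %d", *neq, N);

  for (n = 0; n < N; n++) {
    const double Yn = parms[PAR_Y0 + n];
    double capture, consume;

    dU_s[n] = parms[PAR_K_US] * W[n] * Yn * (1.0 - U_s[n]) -
              parms[PAR_BETA_US] * U_s[n];
    drive += parms[PAR_ALPHA_EFF] * parms[PAR_BETA_US] * U_s[n];

    dT_p[n] = parms[PAR_K_TP] * W[n] *
                hillf(U_s[n], parms[PAR_KK_TP], parms[PAR_H_TP]) *
                (1.0 - T_p[n]) -
              (T_p[n] - parms[PAR_MU_TP]) / parms[PAR_TAU_TP];

    capture = parms[PAR_K_PS] *
              hillf(P_d * T_p[n], parms[PAR_KK_PS], parms[PAR_H_PS]);
    consume = parms[PAR_K_Z] *
              hillf(P_s[n], parms[PAR_KK_Z], parms[PAR_H_Z]) *
              (W[n] - Z[n]);
    dP_s[n] = capture - parms[PAR_BETA_PS] * P_s[n] - consume;
    dZ[n] = consume;
    cap_sum += capture;
    eff_sum += parms[PAR_BETA_PS] * P_s[n];

    dW[n] = parms[PAR_K_W] *
              hillf(U_s[n], parms[PAR_KK_W], parms[PAR_H_W]) *
              (1.0 + U_d) -
            W[n] * (W[n] - Z[n]) / parms[PAR_TAU_W];
  }

  ydot[0] = parms[PAR_K_UD] *
              hillf(drive, parms[PAR_KK_UD], parms[PAR_H_UD]) *
              (1.0 - U_d) -
            parms[PAR_BETA_UD] * U_d;

  synth = parms[PAR_K_PD] * hillf(U_d, parms[PAR_KK_PD], parms[PAR_H_PD]) *
          M_d;
  ydot[1] = -(M_d - parms[PAR_MU_MD]) / parms[PAR_TAU_MD] - synth;
  ydot[2] = -(P_d - parms[PAR_MU_PD]) / parms[PAR_TAU_PD] + synth -
            cap_sum + eff_sum;
}

static const R_CMethodDef CEntries[] = {
  {"stc_derivs", (DL_FUNC) &stc_derivs, 6},
  {"stc_init",   (DL_FUNC) &stc_init,   1},
  {NULL, NULL, 0}
};

void R_init_stcsim(DllInfo *dll)
{
  R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
  R_useDynamicSymbols(dll, TRUE);
}
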