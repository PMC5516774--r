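/* Right-hand side of the chondrocyte oxidative-stress ODE system for deSolve.
   Parameter vector order (14):
   k_S, delta_D, alpha_M, k_D, delta_R, s_C, alpha, k_E, lambda_E, R_0,
   epsilon, delta_E, k_U, lambda_U */
#include <R.h>
#include <math.h>

static double parms[14];
#define k_S      parms[0]
#define delta_D  parms[1]
#define alpha_M  parms[2]
#define k_D      parms[3]
#define delta_R  parms[4]
#define s_C      parms[5]
#define alpha    parms[6]
#define k_E      parms[7]
#define lambda_E parms[8]
#define R_0      parms[9]
#define epsilon  parms[10]
#define delta_E  parms[11]
#define k_U      parms[12]
#define lambda_U parms[13]

void cartox_initmod(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, parms);
}

void cartox_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double M = y[0], D = y[1], R = y[2], E = y[3], U = y[4];
    double S = (R > 1.0) ? s_C * pow(R - 1.0, alpha) : 0.0;
    double x = R / (M + D + epsilon);
    double fE = 0.0;
    if (x > 0.0 && x < 2.0 * R_0) {
        double dx = x - R_0;
        fE = k_E / (dx * dx + lambda_E) - k_E / (R_0 * R_0 + lambda_E);
    }
    ydot[0] = -k_S * M * S;
    ydot[1] =  k_S * M * S - delta_D * D * S;
    ydot[2] =  alpha_M * (M + k_D * D) - delta_R * R;
    ydot[3] =  fE - delta_E * E;
    ydot[4] =  k_U * U * (1.0 - (1.0 + lambda_U) / (1.0 + lambda_U * E) * U);
}
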