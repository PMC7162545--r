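/* Right-hand side of the compartmental Dl/Cact/Toll model, in the form
 * deSolve expects from compiled models (initfunc + derivs).
 *
 * State layout: y = (u_1..u_n, w_1..w_n), u = free cytoplasmic Dl,
 * w = Dl/Cact complex.  Compartment centres x_h = (h-1)/(n-1) span the
 * ventral (0) to dorsal (1) half-circumference; zero-flux ends are imposed
 * with ghost nodes equal to the boundary value, so the plain sum of u + w
 * is conserved whenever a2 = a5 and a3 = a6.
 */
#include <R.h>
#include <math.h>

/* n, lambda_d, lambda_dc, beta0, phi_toll, gamma, kappa, a1..a6 */
#define NPARMS 13
static double parms[NPARMS];

void init_dlcact(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void derivs_dlcact(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const int n = (int) parms[0];
    const double lambda_d  = parms[1];
    const double lambda_dc = parms[2];
    const double beta0     = parms[3];
    const double phi_toll  = parms[4];
    const double gamma     = parms[5];
    const double kappa     = parms[6];
    const double a1 = parms[7], a2 = parms[8],  a3 = parms[9];
    const double a4 = parms[10], a5 = parms[11], a6 = parms[12];
    const double dx = 1.0 / (n - 1);

    const double *u = y;
    const double *w = y + n;
    double *du = ydot;
    double *dw = ydot + n;

    for (int h = 0; h < n; h++) {
        double um = (h == 0)     ? u[0]     : u[h - 1];
        double up = (h == n - 1) ? u[n - 1] : u[h + 1];
        double wm = (h == 0)     ? w[0]     : w[h - 1];
        double wp = (h == n - 1) ? w[n - 1] : w[h + 1];

        double x = h * dx;
        double z = x / phi_toll;
        double beta = beta0 * exp(-z * z);
        double toll = beta * w[h] / (kappa + w[h]);

        du[h] = a1 * lambda_d  * (um - 2.0 * u[h] + up) + a2 * toll
              - a3 * gamma * u[h];
        dw[h] = a4 * lambda_dc * (wm - 2.0 * w[h] + wp) - a5 * toll
              + a6 * gamma * u[h];
    }
}
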