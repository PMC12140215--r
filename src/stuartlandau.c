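/* Stuart-Landau oscillator with sinusoidal external drive, for deSolve.
 *
 *   dx/dt = lambda*x - omega*y - gamma*(x^2+y^2)*x + k*s(t)
 *   dy/dt = lambda*y + omega*x - gamma*(x^2+y^2)*y
 *
 * s(t) = sin(2*pi*fdrive*(t - onset)) for t >= onset, else 0.
 * parms: lambda, omega (rad/s), gamma, kdrive (absolute), fdrive (Hz), onset (s)
 */
#include <R.h>
#include <math.h>

static double parms[6];
#define p_lambda parms[0]
#define p_omega  parms[1]
#define p_gamma  parms[2]
#define p_kdrive parms[3]
#define p_fdrive parms[4]
#define p_onset  parms[5]

void sl_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void sl_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double s = (*t >= p_onset && p_kdrive != 0.0)
        ? sin(2.0 * M_PI * p_fdrive * (*t - p_onset)) : 0.0;
    double r2 = y[0] * y[0] + y[1] * y[1];
    ydot[0] = p_lambda * y[0] - p_omega * y[1] - p_gamma * r2 * y[0]
        + p_kdrive * s;
    ydot[1] = p_lambda * y[1] + p_omega * y[0] - p_gamma * r2 * y[1];
}
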