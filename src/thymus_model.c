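/* Compiled right-hand side of the five-compartment delayed thymocyte model,
 * in the deSolve compiled-code interface. The lagged DN count N(t - tau_N)
 * is supplied by deSolve as a (linearly interpolated) forcing built from the
 * stored solution history, which is what makes the method-of-steps windows
 * plain ODE solves.
 *
 * Parameter vector layout (see rhs_parms() on the R side):
 *  0..3   b_N, b_P, b_4, b_8      proliferation decay rates
 *  4..6   c_N, c_P, c_48          proliferation amplitudes
 *  7..11  s_N, s_4, s_8, s_04, s_08
 * 12..15  d_N, d_P, d_4, d_8
 * 16      delta
 * 17      t_ref   reference time of the proliferation-decay clock
 * 18      model class flag: 1 = M1, 2 = M2
 * 19..20  K_N, K  carrying capacities (M2 only)
 * 21      influx mode: 0 = zero, 1 = logistic, 2 = constant b0
 * 22..24  b0, beta, tau_b
 * 25      delay convention: 0 = arrival delayed, 1 = both delayed
 * 26      lag source: 0 = forcing, 1 = current N (used when tau_N = 0)
 */

#include <math.h>

#define N_PARMS 27

static double parms[N_PARMS];
static double forc[1];

void thymodyn_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void thymodyn_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void thymodyn_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const double *bb = parms;       /* decay rates      */
    const double *cc = parms + 4;   /* amplitudes       */
    const double s_N = parms[7], s_4 = parms[8], s_8 = parms[9];
    const double s_04 = parms[10], s_08 = parms[11];
    const double d_N = parms[12], d_P = parms[13];
    const double d_4 = parms[14], d_8 = parms[15];
    const double delta = parms[16], t_ref = parms[17];
    const int m2 = parms[18] > 1.5;
    const double K_N = parms[19], K = parms[20];
    const int influx_mode = (int) parms[21];
    const double b0 = parms[22], beta = parms[23], tau_b = parms[24];
    const int both_delayed = parms[25] > 0.5;
    const int lag_is_current = parms[26] > 0.5;

    const double N = y[0], P = y[1], S4 = y[2], S8 = y[3], D = y[4];
    const double Nlag = lag_is_current ? N : forc[0];
    const double dt = *t - t_ref;

    double p_N = cc[0] * bb[0] * exp(-bb[0] * dt);
    double p_P = cc[1] * bb[1] * exp(-bb[1] * dt);
    double p_4 = cc[2] * bb[2] * exp(-bb[2] * dt);
    double p_8 = cc[2] * bb[3] * exp(-bb[3] * dt);
    if (m2) {
        const double dens_N = 1.0 - N / K_N;
        const double dens_live = 1.0 - (P + S4 + S8) / K;
        p_N *= dens_N;
        p_P *= dens_live;
        p_4 *= dens_live;
        p_8 *= dens_live;
    }

    double b_t = 0.0;
    if (influx_mode == 1)
        b_t = b0 / (1.0 + exp(-beta * (*t - tau_b)));
    else if (influx_mode == 2)
        b_t = b0;

    const double out_N = both_delayed ? Nlag : N;

    ydot[0] = p_N * N - d_N * N - s_N * out_N + b_t;
    ydot[1] = p_P * P - d_P * P - (s_4 + s_8) * P + s_N * Nlag;
    ydot[2] = p_4 * S4 - d_4 * S4 - s_04 * S4 + s_4 * P;
    ydot[3] = p_8 * S8 - d_8 * S8 - s_08 * S8 + s_8 * P;
    ydot[4] = d_N * N + d_P * P + d_4 * S4 + d_8 * S8 - delta * D;
}
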