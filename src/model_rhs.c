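/* Right-hand side of the five-variable mutual-inhibition ecosystem model,
 * in the form expected by deSolve's compiled-model interface.
 *
 * State order:  N_CB, N_SB, O, S, P
 * Parameter order (must match .symtip_parm_order in R/simulate.R):
 *   g_max, k_P, H_S, H_O, y_P, p_O, p_S, m, alpha_P, O_b, S_b, P_b, c,
 *   a_O, a_S
 *
 * Rate terms are evaluated on states clamped at zero so that transient
 * sub-zero excursions of the integrator cannot produce spurious growth or
 * oxidation; the diffusion terms use the raw state so that any such
 * excursion relaxes back toward the (positive) background concentration.
 */
#include <R.h>

static double parms[15];

#define g_max   parms[0]
#define k_P     parms[1]
#define H_S     parms[2]
#define H_O     parms[3]
#define y_P     parms[4]
#define p_O     parms[5]
#define p_S     parms[6]
#define m_rate  parms[7]
#define alpha_P parms[8]
#define O_b     parms[9]
#define S_b     parms[10]
#define P_b     parms[11]
#define c_ox    parms[12]
#define a_O     parms[13]
#define a_S     parms[14]

void symtip_init(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

void symtip_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double NCB = y[0] > 0 ? y[0] : 0;
    double NSB = y[1] > 0 ? y[1] : 0;
    double O   = y[2] > 0 ? y[2] : 0;
    double S   = y[3] > 0 ? y[3] : 0;
    double P   = y[4] > 0 ? y[4] : 0;

    double g  = g_max * P / (k_P + P);
    double hS = 1.0 / (1.0 + S / H_S);
    double hO = 1.0 / (1.0 + O / H_O);
    double ox = c_ox * O * S;

    ydot[0] = g * hS * NCB - m_rate * NCB;
    ydot[1] = g * hO * NSB - m_rate * NSB;
    ydot[2] = p_O * g * hS * NCB - ox + a_O * (O_b - y[2]);
    ydot[3] = p_S * g * hO * NSB - ox + a_S * (S_b - y[3]);
    ydot[4] = -(g * hS * NCB + g * hO * NSB) / y_P + alpha_P * (P_b - y[4]);
}
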