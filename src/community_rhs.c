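/* Compiled right-hand side of the community ODE system for deSolve.
 *
 * State order (13): X_RI, X_FP, X_BH, Q_RI, Q_FP, Q_BH, S_fructose,
 * S_formate, S_acetate, S_butyrate, S_unknown, S_H2, S_CO2.
 * Parameter order (30): as returned by syngut::parameter_names().
 * Monod terms clip negative concentrations to zero.
 */
#include <R.h>

static double parms[30];

#define mu_RI        parms[0]
#define K_RI_fru     parms[1]
#define K_RI_ace     parms[2]
#define omega_RI     parms[3]
#define nu_RI_fru    parms[4]
#define nu_RI_ace    parms[5]
#define a_RI_for     parms[6]
#define a_RI_but     parms[7]
#define a_RI_H2      parms[8]
#define a_RI_CO2     parms[9]
#define mu_FP        parms[10]
#define K_FP_unk     parms[11]
#define K_FP_fru     parms[12]
#define K_FP_ace     parms[13]
#define omega_FP     parms[14]
#define nu_FP_fru    parms[15]
#define nu_FP_ace    parms[16]
#define nu_FP_unk    parms[17]
#define a_FP_for     parms[18]
#define a_FP_but     parms[19]
#define a_FP_CO2     parms[20]
#define mu_BH        parms[21]
#define K_BH_fru     parms[22]
#define K_BH_for     parms[23]
#define omega_BH     parms[24]
#define nu_BH_fru    parms[25]
#define nu_BH_for    parms[26]
#define a_BH_ace     parms[27]
#define a_BH_H2      parms[28]
#define a_BH_CO2     parms[29]

void community_init(void (*odeparms)(int *, double *))
{
    int n = 30;
    odeparms(&n, parms);
}

static double monod(double s, double k)
{
    if (s < 0.0) s = 0.0;
    return s / (k + s);
}

void community_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double g_RI = y[3] / (1.0 + y[3]);
    double g_FP = y[4] / (1.0 + y[4]);
    double g_BH = y[5] / (1.0 + y[5]);

    double m_fru_RI = monod(y[6], K_RI_fru);
    double m_ace_RI = monod(y[8], K_RI_ace);
    double m_unk_FP = monod(y[10], K_FP_unk);
    double m_fru_FP = monod(y[6], K_FP_fru);
    double m_ace_FP = monod(y[8], K_FP_ace);
    double m_fru_BH = monod(y[6], K_BH_fru);
    double m_for_BH = monod(y[7], K_BH_for);

    double phi_RI = g_RI * mu_RI * m_fru_RI * (1.0 + omega_RI * m_ace_RI);
    double phi_FP = g_FP * mu_FP * m_unk_FP * m_fru_FP *
        (1.0 + omega_FP * m_ace_FP);
    double phi_BH_fru = g_BH * mu_BH * m_fru_BH;
    double phi_BH_for = g_BH * mu_BH * omega_BH * m_for_BH;
    double phi_BH = phi_BH_fru + phi_BH_for;
    double phi_RI_ace = g_RI * mu_RI * omega_RI * m_fru_RI * m_ace_RI;
    double phi_FP_ace = g_FP * mu_FP * omega_FP * m_unk_FP * m_fru_FP *
        m_ace_FP;

    double gRI_X = phi_RI * y[0];
    double gFP_X = phi_FP * y[1];
    double gBH_X = phi_BH * y[2];

    ydot[0] = gRI_X;
    ydot[1] = gFP_X;
    ydot[2] = gBH_X;
    ydot[3] = mu_RI * y[3];
    ydot[4] = mu_FP * y[4];
    ydot[5] = mu_BH * y[5];
    ydot[6] = -nu_RI_fru * gRI_X - nu_FP_fru * gFP_X -
        nu_BH_fru * phi_BH_fru * y[2];
    ydot[7] = a_RI_for * gRI_X + a_FP_for * gFP_X -
        nu_BH_for * phi_BH_for * y[2];
    ydot[8] = -nu_RI_ace * phi_RI_ace * y[0] -
        nu_FP_ace * phi_FP_ace * y[1] + a_BH_ace * gBH_X;
    ydot[9] = a_RI_but * gRI_X + a_FP_but * gFP_X;
    ydot[10] = -nu_FP_unk * gFP_X;
    ydot[11] = a_RI_H2 * gRI_X + a_BH_H2 * gBH_X;
    ydot[12] = a_RI_CO2 * gRI_X + a_FP_CO2 * gFP_X + a_BH_CO2 * gBH_X;
}
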