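/* Coupled liquid + headspace batch fermentation model.
 *
 * States y[0..12]:
 *   0 X, 1 G, 2 Ac, 3 Lac, 4 H2aq, 5 CO2aq, 6 CO2sol      (mol/L liquid)
 *   7 H2G, 8 CO2G, 9 N2G                                   (mol/L gas)
 *  10 cum_h2_out (mol), 11 cum_h2_prod (mol/L liquid),
 *  12 cum_glc_cons (mol/L liquid)
 *
 * Parameters (same order as the R side, see rhs_parameter_vector()):
 *   0 mu_max, 1 K_G, 2 Y_GX, 3 Y_GH2, 4 Y_GAc, 5 Y_GLac, 6 Y_GCO2,
 *   7 R_AcF, 8 R_LacF_H2, 9 R_LacF_OSM, 10 H2aq_crit, 11 n_H2,
 *  12 OSM_crit, 13 n_mu, 14 r_cd, 15 OSM_background, 16 beta,
 *  17 V_l, 18 V_g, 19 P_tot, 20 T, 21 pH, 22 R_gas, 23 H_H2, 24 H_CO2,
 *  25 K1, 26 K2, 27 k_carb, 28 F_in_N2, 29 kla_H2, 30 kla_CO2
 */
#include <R.h>
#include <math.h>

#define NPARMS 31
static double parms[NPARMS];

#define p_mu_max   parms[0]
#define p_K_G      parms[1]
#define p_Y_GX     parms[2]
#define p_Y_GH2    parms[3]
#define p_Y_GAc    parms[4]
#define p_Y_GLac   parms[5]
#define p_Y_GCO2   parms[6]
#define p_R_AcF    parms[7]
#define p_R_LacF_H2  parms[8]
#define p_R_LacF_OSM parms[9]
#define p_H2crit   parms[10]
#define p_n_H2     parms[11]
#define p_OSMcrit  parms[12]
#define p_n_mu     parms[13]
#define p_r_cd     parms[14]
#define p_OSM_bg   parms[15]
#define p_beta     parms[16]
#define p_V_l      parms[17]
#define p_V_g      parms[18]
#define p_P_tot    parms[19]
#define p_T        parms[20]
#define p_pH       parms[21]
#define p_R_gas    parms[22]
#define p_H_H2     parms[23]
#define p_H_CO2    parms[24]
#define p_K1       parms[25]
#define p_K2       parms[26]
#define p_k_carb   parms[27]
#define p_F_in_N2  parms[28]
#define p_kla_H2   parms[29]
#define p_kla_CO2  parms[30]

void h2ferm_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void h2ferm_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double X, G, Ac, Lac, H2aq, CO2aq, CO2sol, H2G, CO2G, N2G;
    double osm, monod, ratio, act_h2, inhib_h2, act_osm, osm_f, mu;
    double a_Ac, a_Lac, a_H2, a_CO2, gflux;
    double RT, P_H2, P_CO2, t_h2, t_co2, carb_target, carb_rate;
    double n_in, n_out, ctot, y_h2, y_co2, y_n2;
    double out_h2, out_co2, out_n2, dG;

    /* integration may probe marginally negative values; treat as zero */
    X      = y[0] > 0 ? y[0] : 0;
    G      = y[1] > 0 ? y[1] : 0;
    Ac     = y[2] > 0 ? y[2] : 0;
    Lac    = y[3] > 0 ? y[3] : 0;
    H2aq   = y[4] > 0 ? y[4] : 0;
    CO2aq  = y[5] > 0 ? y[5] : 0;
    CO2sol = y[6] > 0 ? y[6] : 0;
    H2G    = y[7] > 0 ? y[7] : 0;
    CO2G   = y[8] > 0 ? y[8] : 0;
    N2G    = y[9] > 0 ? y[9] : 0;

    osm = G + 2.0 * Ac + 2.0 * CO2sol + 2.0 * Lac + p_OSM_bg;
    monod = G > 0 ? G / (G + p_K_G) : 0.0;

    ratio = H2aq / p_H2crit;
    act_h2 = ratio >= 1.0 ? 1.0 : pow(ratio, p_n_H2);
    inhib_h2 = 1.0 - act_h2;

    act_osm = pow(osm / p_OSMcrit, p_n_mu);
    osm_f = 1.0 - act_osm;
    if (osm_f < 0.0) osm_f = 0.0;

    mu = p_mu_max * monod * osm_f * inhib_h2;
    if (mu < 0.0) mu = 0.0;

    a_Ac  = p_R_AcF * inhib_h2;
    a_Lac = p_R_LacF_H2 * act_h2 + p_R_LacF_OSM * act_osm;
    a_H2  = a_Ac * (p_Y_GH2 / p_Y_GAc);
    a_CO2 = a_H2 * (p_Y_GCO2 / p_Y_GH2);

    gflux = mu * X;

    RT = p_R_gas * p_T;
    P_H2  = H2G * RT;
    P_CO2 = CO2G * RT;
    t_h2  = p_kla_H2  * (H2aq  - p_H_H2  * P_H2);
    t_co2 = p_kla_CO2 * (CO2aq - p_H_CO2 * P_CO2);

    carb_target = CO2aq * (pow(10.0, p_pH - p_K1) +
                           pow(10.0, 2.0 * p_pH - p_K1 - p_K2));
    carb_rate = p_k_carb * (carb_target - CO2sol);

    dG = -(1.0 / p_Y_GX + a_Ac / p_Y_GAc + a_Lac / p_Y_GLac) * gflux;
    if (G <= 0.0) dG = 0.0;

    ydot[0] = (mu - p_r_cd) * X;
    ydot[1] = dG;
    ydot[2] = a_Ac * gflux + p_beta * X;
    ydot[3] = a_Lac * gflux + p_beta * X;
    ydot[4] = a_H2 * gflux - t_h2;
    ydot[5] = a_CO2 * gflux - t_co2 - carb_rate;
    ydot[6] = carb_rate;

    /* constant-pressure outflow closure */
    n_in = p_F_in_N2 * p_P_tot / RT;
    n_out = n_in + p_V_l * (t_h2 + t_co2);
    if (n_out < 0.0) n_out = 0.0;
    ctot = H2G + CO2G + N2G;
    if (ctot > 0.0) {
        y_h2 = H2G / ctot; y_co2 = CO2G / ctot; y_n2 = N2G / ctot;
    } else {
        y_h2 = y_co2 = y_n2 = 0.0;
    }
    out_h2 = n_out * y_h2;
    out_co2 = n_out * y_co2;
    out_n2 = n_out * y_n2;

    ydot[7] = (p_V_l * t_h2  - out_h2)  / p_V_g;
    ydot[8] = (p_V_l * t_co2 - out_co2) / p_V_g;
    ydot[9] = (n_in - out_n2) / p_V_g;

    ydot[10] = out_h2;          /* mol H2 leaving with the off-gas per h */
    ydot[11] = a_H2 * gflux;    /* produced H2, liquid basis */
    ydot[12] = -dG;             /* consumed glucose */

    if (ip[0] >= 16) {
        yout[0]  = mu;
        yout[1]  = osm;
        yout[2]  = inhib_h2;
        yout[3]  = act_h2;
        yout[4]  = act_osm;
        yout[5]  = a_Ac;
        yout[6]  = a_Lac;
        yout[7]  = a_H2;
        yout[8]  = a_CO2;
        yout[9]  = t_h2;
        yout[10] = t_co2;
        yout[11] = carb_rate;
        yout[12] = out_h2  * RT / p_P_tot;   /* F_out_H2, L/h */
        yout[13] = out_co2 * RT / p_P_tot;
        yout[14] = out_n2  * RT / p_P_tot;
        yout[15] = a_H2 * gflux;             /* volumetric H2 productivity */
    }
}
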