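#include <Rcpp.h>
using namespace Rcpp;

// Daily explicit update of one landscape unit (quick -> soil -> groundwater
// cascade with degree-day snow and evapotranspiration). Within-day order:
//   1. snow partition of precipitation, degree-day melt
//   2. quick bucket gains rain + melt and drains V_q / tau_quick to the soil
//   3. PET = et_rate * max(0, T - et_threshold);
//      AET = PET * min(1, V_s / field_capacity)^et_adjustment, capped at V_s
//   4. soil drainage D = max(0, V_s - field_capacity) / tau_soil, split
//      soil_to_gw to groundwater, remainder to the stream
//   5. groundwater drains V_g / tau_gw to the stream
// Residence times >= 1 day keep every outflow within available storage.
// [[Rcpp::export(name = ".simulate_unit_cpp")]]
List simulate_unit_cpp(NumericVector temp, NumericVector precip,
                       double tau_quick, double tau_soil, double tau_gw,
                       double field_capacity, double soil_to_gw,
                       double et_rate, double et_threshold,
                       double et_adjustment, double melt_rate,
                       double snow_threshold, bool snow_enabled,
                       double init_quick, double init_soil, double init_gw) {
  int n = temp.size();
  if (precip.size() != n) stop("temperature and precipitation differ in length");

  NumericVector runoff(n), aet(n), vq(n), vs(n), vg(n), snow(n);
  double Vq = init_quick, Vs = init_soil, Vg = init_gw, Sp = 0.0;

  for (int t = 0; t < n; ++t) {
    double T = temp[t], P = precip[t];
    if (!R_finite(T) || !R_finite(P))
      stop("non-finite forcing on day %d", t + 1);

    // (1) snow partition and melt
    double rain = P;
    if (snow_enabled && T < snow_threshold) {
      Sp += P;
      rain = 0.0;
    }
    double melt = 0.0;
    if (snow_enabled && Sp > 0.0 && T > snow_threshold) {
      melt = melt_rate * (T - snow_threshold);
      if (melt > Sp) melt = Sp;
      Sp -= melt;
    }

    // (2) quick bucket: all outflow routed to the soil
    Vq += rain + melt;
    double quick_out = Vq / tau_quick;
    Vq -= quick_out;
    Vs += quick_out;

    // (3) evapotranspiration
    double pet = et_rate * std::max(0.0, T - et_threshold);
    double wet = std::min(1.0, Vs / field_capacity);
    double a = pet * std::pow(wet, et_adjustment);
    if (a > Vs) a = Vs;
    Vs -= a;

    // (4) soil drainage above field capacity
    double drain = std::max(0.0, Vs - field_capacity) / tau_soil;
    Vs -= drain;
    double to_gw = soil_to_gw * drain;
    double to_stream = drain - to_gw;

    // (5) groundwater linear reservoir
    Vg += to_gw;
    double gw_out = Vg / tau_gw;
    Vg -= gw_out;

    runoff[t] = to_stream + gw_out;
    aet[t] = a;
    vq[t] = Vq; vs[t] = Vs; vg[t] = Vg; snow[t] = Sp;
  }

  return List::create(_["runoff"] = runoff, _["aet"] = aet,
                      _["quick"] = vq, _["soil"] = vs, _["gw"] = vg,
                      _["snowpack"] = snow);
}
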