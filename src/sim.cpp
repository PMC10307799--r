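// Closed-loop session core: per-frame stimulus controllers and the
// Ornstein-Uhlenbeck fish agent, shared between the exported single-step
// functions (used by the R-level reference loop and the unit tests) and the
// fast full-session loop. All randomness goes through R's RNG so that
// set.seed() in R makes every path reproducible, and so the R and C++ session
// engines consume the identical stream.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double RAD2DEG = 57.29577951308232;

// motion type codes shared with R (R/controllers.R keeps the same map)
enum MotionCode {
  MODE_ABSENT = 0, MODE_MOTIONLESS = 1, MODE_CHASING = 2,
  MODE_FLEEING = 3, MODE_FLIPPED = 4, MODE_INDEPENDENT = 5
};

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// proportional pursuit: step = min(d, d * dt * 1000 / divisor) along pos->target.
// Deadband (strict: moves only when d > deadband) is optional so the fleeing
// relocation can reuse the identical velocity law without it.
static inline bool chase_core(double &u, double &v, double tu, double tv,
                              double dt, double divisor, double deadband,
                              bool use_deadband, double W, double H) {
  double du = tu - u, dv = tv - v;
  double d = std::sqrt(du * du + dv * dv);
  if (d <= 0.0) return false;
  if (use_deadband && d <= deadband) return false;
  double step = d * dt * 1000.0 / divisor;
  if (step > d) step = d;
  u = clampd(u + step * du / d, 0.0, W);
  v = clampd(v + step * dv / d, 0.0, H);
  return step > 0.0;
}

// yaw: 0 = head leftward, 180 = rightward, unchanged on u-tie;
// pitch: elevation of the target in the monitor plane (v axis points down),
// clamped to the animation's limits.
static inline void orient_core(double u, double v, double tu, double tv,
                               double &yaw, double &pitch,
                               double yaw_lo, double yaw_hi,
                               double pit_lo, double pit_hi) {
  if (tu < u) yaw = yaw_lo;
  else if (tu > u) yaw = yaw_hi;
  double du = std::fabs(tu - u), dv = v - tv; // dv > 0: target above
  if (du > 0.0 || dv != 0.0) {
    double elev = std::atan2(dv, du) * RAD2DEG;
    pitch = clampd(elev, pit_lo, pit_hi);
  }
}

// "0 to 2 pixels (randomly selected)" leftward or rightward off the monitor
// center each frame; consumes exactly two uniforms.
static inline void motionless_core(double cu, double cv, double &u, double &v,
                                   double jitter_max) {
  double sgn = unif_rand() < 0.5 ? -1.0 : 1.0;
  double delta = std::floor(unif_rand() * (jitter_max + 1.0));
  if (delta > jitter_max) delta = jitter_max;
  u = cu + sgn * delta;
  v = cv;
}

// fleeing: trigger when |du| <= dx_thr and |dv| <= dy_thr (inclusive) and not
// already relocating; relocation target uniform on the opposite monitor half;
// travel under the chasing velocity law (no deadband) until within arrive_tol.
// Consumes two uniforms on a trigger, none otherwise.
static inline void flee_core(double &u, double &v, double tu, double tv,
                             bool &relocating, double &ru, double &rv,
                             double dt, double divisor,
                             double dx_thr, double dy_thr,
                             double W, double H, bool teleport,
                             double arrive_tol, bool &moved, bool &triggered) {
  moved = false; triggered = false;
  if (!relocating) {
    if (std::fabs(tu - u) <= dx_thr && std::fabs(tv - v) <= dy_thr) {
      if (u < W / 2.0) ru = W / 2.0 + unif_rand() * (W / 2.0);
      else             ru = unif_rand() * (W / 2.0);
      rv = unif_rand() * H;
      relocating = true;
      triggered = true;
    }
  }
  if (relocating) {
    if (teleport) {
      u = ru; v = rv; relocating = false; moved = true;
      return;
    }
    moved = chase_core(u, v, ru, rv, dt, divisor, 0.0, false, W, H);
    double d = std::hypot(ru - u, rv - v);
    if (d <= arrive_tol) relocating = false;
  }
}

// unit vector from head toward a tank-wall midpoint, scaled by kappa
static inline void add_wall_attraction(const double head[3], double k,
                                       double mx, double my, double mz,
                                       double out[3]) {
  if (k == 0.0) return;
  double dx = mx - head[0], dy = my - head[1], dz = mz - head[2];
  double n = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (n <= 0.0) return;
  out[0] += k * dx / n; out[1] += k * dy / n; out[2] += k * dz / n;
}

// OU velocity relaxation toward mean_speed along the current heading, plus
// attraction drift, soft wall repulsion inside wall_margin, and Gaussian
// velocity noise; positions reflected at the tank walls. Consumes exactly
// three normals per call.
static inline void agent_core(double head[3], double vel[3],
                              const double drift[3],
                              double mean_speed, double relax, double noise_sd,
                              double wall_margin, double wall_rep,
                              const double dims[3], double dt) {
  double sp = std::sqrt(vel[0] * vel[0] + vel[1] * vel[1] + vel[2] * vel[2]);
  double pref[3] = {0.0, 0.0, 0.0};
  if (sp > 1e-12) {
    pref[0] = mean_speed * vel[0] / sp;
    pref[1] = mean_speed * vel[1] / sp;
    pref[2] = mean_speed * vel[2] / sp;
  }
  double rep[3] = {0.0, 0.0, 0.0};
  for (int a = 0; a < 3; ++a) {
    if (head[a] < wall_margin)
      rep[a] += wall_rep * (1.0 - head[a] / wall_margin);
    if (head[a] > dims[a] - wall_margin)
      rep[a] -= wall_rep * (1.0 - (dims[a] - head[a]) / wall_margin);
  }
  double sq = std::sqrt(dt);
  for (int a = 0; a < 3; ++a) {
    vel[a] += relax * (pref[a] - vel[a]) * dt + (drift[a] + rep[a]) * dt +
              noise_sd * sq * norm_rand();
  }
  for (int a = 0; a < 3; ++a) {
    head[a] += vel[a] * dt;
    // reflect at the walls (repeat in case of extreme steps)
    int guard = 0;
    while ((head[a] < 0.0 || head[a] > dims[a]) && guard++ < 8) {
      if (head[a] < 0.0) { head[a] = -head[a]; vel[a] = -vel[a]; }
      if (head[a] > dims[a]) { head[a] = 2.0 * dims[a] - head[a]; vel[a] = -vel[a]; }
    }
    head[a] = clampd(head[a], 0.0, dims[a]);
  }
}

// ---------------------------------------------------------------- exported

// [[Rcpp::export]]
NumericVector cpp_chase_step(double u, double v, double tu, double tv,
                             double dt, double deadband, double divisor,
                             double W, double H, bool use_deadband = true) {
  bool moved = chase_core(u, v, tu, tv, dt, divisor, deadband, use_deadband, W, H);
  return NumericVector::create(u, v, moved ? 1.0 : 0.0);
}

// [[Rcpp::export]]
NumericVector cpp_orient_toward(double u, double v, double tu, double tv,
                                double yaw, double pitch,
                                double yaw_lo, double yaw_hi,
                                double pit_lo, double pit_hi) {
  orient_core(u, v, tu, tv, yaw, pitch, yaw_lo, yaw_hi, pit_lo, pit_hi);
  return NumericVector::create(yaw, pitch);
}

// [[Rcpp::export]]
NumericVector cpp_motionless_step(double cu, double cv, double jitter_max) {
  double u, v;
  motionless_core(cu, cv, u, v, jitter_max);
  return NumericVector::create(u, v);
}

// [[Rcpp::export]]
NumericVector cpp_flee_step(double u, double v, double tu, double tv,
                            bool relocating, double ru, double rv,
                            double dt, double divisor,
                            double dx_thr, double dy_thr,
                            double W, double H, bool teleport,
                            double arrive_tol) {
  bool moved, triggered;
  flee_core(u, v, tu, tv, relocating, ru, rv, dt, divisor, dx_thr, dy_thr,
            W, H, teleport, arrive_tol, moved, triggered);
  return NumericVector::create(u, v, relocating ? 1.0 : 0.0, ru, rv,
                               moved ? 1.0 : 0.0, triggered ? 1.0 : 0.0);
}

// [[Rcpp::export]]
NumericVector cpp_attraction_drift(NumericVector head, double kL, double kR,
                                   double tank_length, double tank_width,
                                   double water_depth) {
  double h[3] = {head[0], head[1], head[2]};
  double out[3] = {0.0, 0.0, 0.0};
  add_wall_attraction(h, kL, 0.0, tank_width / 2.0, water_depth / 2.0, out);
  add_wall_attraction(h, kR, tank_length, tank_width / 2.0, water_depth / 2.0, out);
  return NumericVector::create(out[0], out[1], out[2]);
}

// [[Rcpp::export]]
NumericVector cpp_agent_step(NumericVector head, NumericVector vel,
                             NumericVector drift, double mean_speed,
                             double relax, double noise_sd,
                             double wall_margin, double wall_rep,
                             NumericVector dims, double dt) {
  double h[3] = {head[0], head[1], head[2]};
  double v[3] = {vel[0], vel[1], vel[2]};
  double dr[3] = {drift[0], drift[1], drift[2]};
  double dm[3] = {dims[0], dims[1], dims[2]};
  agent_core(h, v, dr, mean_speed, relax, noise_sd, wall_margin, wall_rep, dm, dt);
  return NumericVector::create(h[0], h[1], h[2], v[0], v[1], v[2]);
}

// Full closed-loop session. Frame order: record fish state, update left then
// right stimulus from the fish's projected head, then step the agent against
// the fresh stimulus states. Stimuli exist only on frames in
// [vis_start, vis_end) and only for non-absent modes. Packed parameter
// vectors (assembled by R/session.R):
//   geom:   L, W, D, mon_W, mon_H, px_per_cm
//   ctrl:   dt, deadband, divisor, jitter_max, flee_dx, flee_dy,
//           yaw_lo, yaw_hi, pit_lo, pit_hi, teleport, arrive_tol
//   agentp: mean_speed, relax, noise_sd, wall_margin, wall_rep,
//           kappa_left, kappa_right, salience_bonus, salience_frames
// [[Rcpp::export]]
List cpp_simulate_session(int n_frames, int vis_start, int vis_end,
                          int left_mode, int right_mode,
                          NumericMatrix left_track, NumericMatrix right_track,
                          NumericVector geom, NumericVector ctrl,
                          NumericVector agentp,
                          NumericVector start_head, NumericVector start_vel) {
  const double L = geom[0], W = geom[1], D = geom[2];
  const double mW = geom[3], mH = geom[4], s = geom[5];
  const double dt = ctrl[0], deadband = ctrl[1], divisor = ctrl[2];
  const double jitter_max = ctrl[3], flee_dx = ctrl[4], flee_dy = ctrl[5];
  const double yaw_lo = ctrl[6], yaw_hi = ctrl[7];
  const double pit_lo = ctrl[8], pit_hi = ctrl[9];
  const bool teleport = ctrl[10] != 0.0;
  const double arrive_tol = ctrl[11];
  const double mean_speed = agentp[0], relax = agentp[1], noise_sd = agentp[2];
  const double wall_margin = agentp[3], wall_rep = agentp[4];
  const double kapL = agentp[5], kapR = agentp[6];
  const double bonus = agentp[7];
  const int sal_frames = (int)agentp[8];
  const double dims[3] = {L, W, D};

  const int modes[2] = {left_mode, right_mode};
  for (int sdx = 0; sdx < 2; ++sdx) {
    if (modes[sdx] == MODE_INDEPENDENT) {
      const NumericMatrix &tr = sdx == 0 ? left_track : right_track;
      if (tr.nrow() < vis_end - vis_start)
        stop("playback track too short for the stimulus period");
    }
  }

  NumericMatrix head(n_frames, 3), vel(n_frames, 3);
  // per-side stimulus record: u, v, yaw, pitch, visible, rel_u, rel_v
  NumericMatrix stimL(n_frames, 7), stimR(n_frames, 7);

  double h[3] = {start_head[0], start_head[1], start_head[2]};
  double v[3] = {start_vel[0], start_vel[1], start_vel[2]};

  double su[2] = {mW / 2.0, mW / 2.0}, sv[2] = {mH / 2.0, mH / 2.0};
  double syaw[2] = {yaw_lo, yaw_lo}, spitch[2] = {0.0, 0.0};
  bool reloc[2] = {false, false};
  double ru[2] = {0.0, 0.0}, rv[2] = {0.0, 0.0};
  int last_moved[2] = {-1000000, -1000000};

  for (int t = 0; t < n_frames; ++t) {
    for (int a = 0; a < 3; ++a) { head(t, a) = h[a]; vel(t, a) = v[a]; }

    const bool in_window = t >= vis_start && t < vis_end;
    double keff[2] = {0.0, 0.0};

    for (int sdx = 0; sdx < 2; ++sdx) {
      const int mode = modes[sdx];
      NumericMatrix &out = sdx == 0 ? stimL : stimR;
      const bool visible = in_window && mode != MODE_ABSENT;
      // mirror-consistent per-side monitor frame (u from each monitor's own
      // left edge), so one controller implementation serves both sides
      const double tu = sdx == 0 ? h[1] * s : (W - h[1]) * s;
      const double tv = (D - h[2]) * s;

      bool moved = false;
      if (visible) {
        switch (mode) {
        case MODE_MOTIONLESS: {
          double pu = su[sdx];
          motionless_core(mW / 2.0, mH / 2.0, su[sdx], sv[sdx], jitter_max);
          syaw[sdx] = yaw_lo; spitch[sdx] = 0.0;
          moved = su[sdx] != pu;
          break;
        }
        case MODE_CHASING: {
          moved = chase_core(su[sdx], sv[sdx], tu, tv, dt, divisor, deadband,
                             true, mW, mH);
          orient_core(su[sdx], sv[sdx], tu, tv, syaw[sdx], spitch[sdx],
                      yaw_lo, yaw_hi, pit_lo, pit_hi);
          break;
        }
        case MODE_FLIPPED: {
          const double mu = mW - tu;
          moved = chase_core(su[sdx], sv[sdx], mu, tv, dt, divisor, deadband,
                             true, mW, mH);
          orient_core(su[sdx], sv[sdx], mu, tv, syaw[sdx], spitch[sdx],
                      yaw_lo, yaw_hi, pit_lo, pit_hi);
          break;
        }
        case MODE_FLEEING: {
          bool trig;
          flee_core(su[sdx], sv[sdx], tu, tv, reloc[sdx], ru[sdx], rv[sdx],
                    dt, divisor, flee_dx, flee_dy, mW, mH, teleport,
                    arrive_tol, moved, trig);
          orient_core(su[sdx], sv[sdx], tu, tv, syaw[sdx], spitch[sdx],
                      yaw_lo, yaw_hi, pit_lo, pit_hi);
          break;
        }
        case MODE_INDEPENDENT: {
          const NumericMatrix &tr = sdx == 0 ? left_track : right_track;
          const int k = t - vis_start;
          double pu = su[sdx], pv = sv[sdx];
          su[sdx] = tr(k, 0); sv[sdx] = tr(k, 1);
          syaw[sdx] = tr(k, 2); spitch[sdx] = tr(k, 3);
          moved = su[sdx] != pu || sv[sdx] != pv;
          break;
        }
        }
        if (moved) last_moved[sdx] = t;
        const bool salient = t - last_moved[sdx] < sal_frames;
        keff[sdx] = (sdx == 0 ? kapL : kapR) * (salient ? bonus : 1.0);
      } else {
        // monitors blank: stimulus parked at center, no attraction
        su[sdx] = mW / 2.0; sv[sdx] = mH / 2.0;
        syaw[sdx] = yaw_lo; spitch[sdx] = 0.0;
        reloc[sdx] = false;
        last_moved[sdx] = -1000000;
      }
      out(t, 0) = su[sdx]; out(t, 1) = sv[sdx];
      out(t, 2) = syaw[sdx]; out(t, 3) = spitch[sdx];
      out(t, 4) = visible ? 1.0 : 0.0;
      out(t, 5) = reloc[sdx] ? ru[sdx] : NA_REAL;
      out(t, 6) = reloc[sdx] ? rv[sdx] : NA_REAL;
    }

    double drift[3] = {0.0, 0.0, 0.0};
    add_wall_attraction(h, keff[0], 0.0, W / 2.0, D / 2.0, drift);
    add_wall_attraction(h, keff[1], L, W / 2.0, D / 2.0, drift);
    agent_core(h, v, drift, mean_speed, relax, noise_sd, wall_margin,
               wall_rep, dims, dt);
  }

  return List::create(_["head"] = head, _["vel"] = vel,
                      _["left"] = stimL, _["right"] = stimR);
}
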