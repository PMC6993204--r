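#' Teleoperation force-feedback parameters
#'
#' Container for the gains of the two haptic feedback controllers and the
#' companion constants of the teleoperation setup: the position-exchange (PE)
#' PD gains, the direct-feedback (DF) force gain, the master-to-patient
#' translation scaling, and the force-sensor noise threshold used by the
#' segmentation stage.
#'
#' @param k_p Stiffness gain of the PE controller, N/m. Default 1000.
#' @param k_d Damping gain of the PE controller, N·s/m. Default 30.
#' @param g_df Direct-feedback scalar gain (dimensionless, in (0, 1]).
#'   Default 0.7.
#' @param s_tele Master-to-patient translation scaling (dimensionless, in
#'   (0, 1]). Default 0.4.
#' @param force_noise_threshold Force-sensor noise threshold, N. Default 0.06.
#' @return An object of class `feedback_params`.
#' @export
#' @examples
#' p <- feedback_params()
#' pe_feedback_force(c(1e-3, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), p)
feedback_params <- function(k_p = 1000, k_d = 30, g_df = 0.7, s_tele = 0.4,
                            force_noise_threshold = 0.06) {
  stopifnot(is.numeric(k_p), k_p >= 0, is.numeric(k_d), k_d >= 0,
            is.numeric(force_noise_threshold), force_noise_threshold >= 0)
  if (!is.numeric(g_df) || g_df <= 0 || g_df > 1)
    stop("`g_df` must be in (0, 1]", call. = FALSE)
  if (!is.numeric(s_tele) || s_tele <= 0 || s_tele > 1)
    stop("`s_tele` must be in (0, 1]", call. = FALSE)
  structure(list(k_p = k_p, k_d = k_d, g_df = g_df, s_tele = s_tele,
                 force_noise_threshold = force_noise_threshold),
            class = "feedback_params")
}

#' Position-exchange (PE) feedback force
#'
#' Force rendered to the operator by the position-exchange PD controller:
#' a stiffness term on the position error between the desired tooltip
#' position (commanded by the master) and the current patient-side position,
#' plus a damping term on the velocity error,
#' `f = k_p * (x_des - x_cur) + k_d * (v_des - v_cur)`.
#'
#' @param x_des,x_cur Desired and current tooltip position, 3-vectors, m.
#' @param v_des,v_cur Desired and current tooltip velocity, 3-vectors, m/s.
#' @param params A [feedback_params()] object.
#' @return Feedback force, 3-vector, N.
#' @export
pe_feedback_force <- function(x_des, x_cur, v_des, v_cur,
                              params = feedback_params()) {
  x_des <- as_vec3(x_des, "x_des"); x_cur <- as_vec3(x_cur, "x_cur")
  v_des <- as_vec3(v_des, "v_des"); v_cur <- as_vec3(v_cur, "v_cur")
  params$k_p * (x_des - x_cur) + params$k_d * (v_des - v_cur)
}

#' Direct force feedback
#'
#' Force rendered to the operator in the direct-feedback condition: the
#' force-sensor reading scaled componentwise by the gain `g_df`.
#'
#' @param f_sensed Sensed tissue-interaction force, 3-vector, N.
#' @param params A [feedback_params()] object.
#' @return Feedback force, 3-vector, N.
#' @export
df_feedback_force <- function(f_sensed, params = feedback_params()) {
  f_sensed <- as_vec3(f_sensed, "f_sensed")
  params$g_df * f_sensed
}
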