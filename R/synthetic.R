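#' Configuration for the synthetic group-movement generator
#'
#' The generator emulates a cohesive terrestrial group tracked at 1 Hz:
#' agents hold a tight formation (offsets within ~1.5 m, matching the high
#' spatial cohesion of the study system), scripted initiation episodes in
#' which one or more initiators walk away and the group follows or not,
#' GPS noise of 0.5 m SD (tags accurate to within ~1 m), occasional
#' single-second dropouts, and rare gross outliers. The behavioural truth
#' (follow-probability coefficients, compromise-to-choose transition
#' angle, majority steepness, male success bias) is planted and returned
#' alongside the trajectories.
#'
#' @param n_agents group size (default 10).
#' @param n_males number of males (default 5; males are the first ids).
#' @param arena half-open square side in metres for the study area.
#' @param day_start epoch seconds of the first fix.
#' @param formation_radius agent offsets from the centroid (m).
#' @param speed walking speed during episodes (m/s).
#' @param catchup_speed speed at which initiators rejoin (m/s).
#' @param jitter_sd stationary SD of within-formation jitter (m).
#' @param gps_noise_sd RMS of each tag's 2D position-error vector (m),
#'   modelled as slowly drifting (AR(1), ~50 s time constant) as GPS error
#'   is at 1 Hz; 0 for noise-free runs.
#' @param missing_rate per-fix probability of a dropped sample (< 0.2).
#' @param n_outliers number of gross outliers planted far outside the
#'   arena.
#' @param quiescence seconds of rest between episodes (>= 60 so chain-rule
#'   aggregation is controllable).
#' @param displacement initiator displacement for single-initiator
#'   episodes (m; well above the 3.5 m detection threshold).
#' @param displacement_multi displacement for multi-initiator episodes
#'   (m; larger so compromise responses still close the gap detectably).
#' @param follow_beta planted logit coefficients c(b0, b1, b2, b3) of
#'   P(follow) ~ b0 + b1 n + b2 A + b3 n A.
#' @param theta_c_deg planted compromise-to-choose transition angle.
#' @param beta_major planted majority-rule logistic steepness (default
#'   reaches P = 0.8 at a cluster-size difference of 4).
#' @param p_male_success probability the male's direction wins in a
#'   mixed-sex two-puller choose event.
#' @param kappa_follower von Mises concentration of follower-direction
#'   noise.
#' @param hierarchy_steepness logistic steepness of the latent dominance
#'   hierarchy.
#' @param episodes data.frame describing the schedule (columns `type`
#'   ("pull", "anchor", "multi"), `initiators` (count), and optionally
#'   `theta_deg`, `n1`, `n2`); or an integer number of episodes to draw a
#'   mixed schedule.
#' @param dropout optional data.frame(t_start, t_end, n_ids) of planted
#'   low-coverage spans (that many tags silent).
#' @param origin_lonlat projection origin for Movebank-style output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_agents = 10, n_males = 5, arena = 2000,
                       day_start = 1677650400L,
                       formation_radius = 1.5, speed = 1, catchup_speed = 2,
                       jitter_sd = 0.15, gps_noise_sd = 0.5,
                       missing_rate = 0.01, n_outliers = 0,
                       quiescence = 60,
                       displacement = 10, displacement_multi = 40,
                       follow_beta = c(0.6, -0.8, 0.5, 1.2),
                       theta_c_deg = 100, beta_major = log(4) / 4,
                       p_male_success = 0.55, kappa_follower = 20,
                       hierarchy_steepness = 10,
                       episodes = 10, dropout = NULL,
                       origin_lonlat = c(36.90, 0.29)) {
  stopifnot(n_agents >= 3, n_males >= 1, n_males < n_agents,
            missing_rate >= 0, missing_rate < 0.2,
            displacement > 2 * 3.5, displacement_multi > 2 * 3.5,
            quiescence >= 60)
  structure(as.list(environment()), class = "sim_config")
}

.sim_ids <- function(cfg) sprintf("W%02d", seq_len(cfg$n_agents))

#' Metadata table implied by a configuration
#' @param cfg a [sim_config()].
#' @return data.frame with id, sex, group.
#' @export
sim_metadata <- function(cfg) {
  ids <- .sim_ids(cfg)
  data.frame(id = ids,
             sex = c(rep("M", cfg$n_males), rep("F", cfg$n_agents - cfg$n_males)),
             group = "G1", stringsAsFactors = FALSE)
}

# draw a mixed schedule when only a count is given
.sim_schedule <- function(cfg) {
  if (is.data.frame(cfg$episodes)) return(cfg$episodes)
  n <- cfg$episodes
  type <- sample(c("pull", "anchor", "multi"), n, replace = TRUE,
                 prob = c(0.4, 0.3, 0.3))
  data.frame(type = type,
             initiators = ifelse(type == "multi", 2L, 1L),
             theta_deg = ifelse(type == "multi",
                                stats::runif(n, 20, 170), NA_real_))
}

#' Simulate a tracked group with scripted initiation episodes
#'
#' Produces a [trajectory_grid()] plus ground-truth tables sufficient to
#' verify every downstream stage without re-simulation. With
#' `gps_noise_sd = 0` and `missing_rate = 0` the recovery of the planted
#' attempts by the extraction pipeline is exact for single-initiator
#' schedules (multi-initiator episodes additionally produce genuine
#' regrouping attempts, which are not enumerated in the truth table).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return list with `grid`, `truth` (data.frame of implied primary
#'   attempts: episode, initiator, follower, outcome, t1, t2, t3),
#'   `episodes` (per-episode table with planted directions, agreement,
#'   follow decision, response direction), `metadata`, `config`.
#' @export
simulate_group <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- .sim_ids(cfg)
  n <- cfg$n_agents
  sched <- .sim_schedule(cfg)
  v <- cfg$speed
  # generous preallocation; trimmed at the end
  dur_guess <- cfg$quiescence + nrow(sched) *
    (cfg$quiescence + 10 * ceiling(cfg$displacement_multi / v) + 60)
  Tn <- dur_guess
  Cx <- numeric(Tn); Cy <- numeric(Tn)
  extra_x <- matrix(0, n, Tn); extra_y <- matrix(0, n, Tn)
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- cfg$formation_radius * sqrt(stats::runif(n))
  off_x <- rad * cos(ang); off_y <- rad * sin(ang)
  C_cur <- c(cfg$arena / 2, cfg$arena / 2)
  t_cur <- 1L
  hold_centroid <- function(dur) {
    idx <- t_cur:(t_cur + dur - 1L)
    Cx[idx] <<- C_cur[1]; Cy[idx] <<- C_cur[2]
    t_cur <<- t_cur + dur
  }
  move_centroid <- function(u, dist) {
    dur <- ceiling(dist / v)
    idx <- t_cur:(t_cur + dur - 1L)
    frac <- seq_len(dur) / dur
    Cx[idx] <<- C_cur[1] + u[1] * dist * frac
    Cy[idx] <<- C_cur[2] + u[2] * dist * frac
    C_cur <<- C_cur + u * dist
    t_cur <<- t_cur + dur
  }
  # move selected agents' extra offsets linearly from their current value
  # to a target, over dur seconds, while the centroid holds; the reached
  # target persists until overwritten
  move_extra <- function(agents, targets_x, targets_y, dur) {
    idx <- t_cur:(t_cur + dur - 1L)
    frac <- seq_len(dur) / dur
    for (a in seq_along(agents)) {
      i <- agents[a]
      x0 <- extra_x[i, t_cur - 1L]; y0 <- extra_y[i, t_cur - 1L]
      extra_x[i, idx] <<- x0 + (targets_x[a] - x0) * frac
      extra_y[i, idx] <<- y0 + (targets_y[a] - y0) * frac
      extra_x[i, (t_cur + dur - 1L):Tn] <<- targets_x[a]
      extra_y[i, (t_cur + dur - 1L):Tn] <<- targets_y[a]
    }
    Cx[idx] <<- C_cur[1]; Cy[idx] <<- C_cur[2]
    t_cur <<- t_cur + dur
  }
  truth <- list(); eps <- list()
  hold_centroid(cfg$quiescence)
  for (e in seq_len(nrow(sched))) {
    type <- sched$type[e]
    t0 <- t_cur
    if (type %in% c("pull", "anchor")) {
      init <- sample.int(n, 1)
      fol <- setdiff(seq_len(n), init)
      phi <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(phi), sin(phi))
      D <- cfg$displacement
      dur1 <- ceiling(D / v)
      move_extra(init, u[1] * D, u[2] * D, dur1)   # initiator walks out
      t2 <- t_cur - 1L
      hold_centroid(4L)                            # decision pause
      if (type == "anchor") {
        move_extra(init, 0, 0, dur1)               # initiator returns
        t3 <- t_cur - 1L
      } else {
        # group translates to the initiator; initiator holds absolute
        # position by compensating the centroid shift
        idx0 <- t_cur
        move_centroid(u, D)
        idx <- idx0:(t_cur - 1L)
        extra_x[init, idx] <- extra_x[init, idx0 - 1L] - (Cx[idx] - Cx[idx0 - 1L])
        extra_y[init, idx] <- extra_y[init, idx0 - 1L] - (Cy[idx] - Cy[idx0 - 1L])
        extra_x[init, t_cur:Tn] <- extra_x[init, t_cur - 1L]
        extra_y[init, t_cur:Tn] <- extra_y[init, t_cur - 1L]
        t3 <- t_cur - 1L
      }
      truth[[e]] <- data.frame(episode = e, initiator = ids[init],
                               follower = ids[fol], outcome = type,
                               t1 = t0 - 1L, t2 = t2, t3 = t3)
      eps[[e]] <- data.frame(episode = e, type = type, n_initiators = 1L,
                             t_start = t0, agreement = 1,
                             followed = type == "pull",
                             theta_deg = NA_real_,
                             response_deg = if (type == "pull") phi * 180 / pi else NA_real_)
    } else {
      # multi-initiator episode (two initiators, or two clusters when
      # n1/n2 are supplied)
      has_clusters <- all(c("n1", "n2") %in% names(sched)) &&
        !is.na(sched$n1[e])
      phi <- stats::runif(1, 0, 2 * pi)
      theta <- (if (!is.na(sched$theta_deg[e])) sched$theta_deg[e]
                else stats::runif(1, 20, 170)) * pi / 180
      if (has_clusters) {
        n1 <- sched$n1[e]; n2 <- sched$n2[e]
        members <- sample.int(n, n1 + n2)
        dirs <- c(phi + theta / 2 + stats::runif(n1, -0.14, 0.14),
                  phi - theta / 2 + stats::runif(n2, -0.14, 0.14))
        cluster <- rep(1:2, c(n1, n2))
      } else {
        n1 <- 1L; n2 <- 1L
        members <- sample.int(n, 2)
        dirs <- c(phi + theta / 2, phi - theta / 2)
        cluster <- 1:2
      }
      k <- length(members)
      fol <- setdiff(seq_len(n), members)
      D <- cfg$displacement_multi
      dur1 <- ceiling(D / v)
      A <- resultant_length(dirs)
      b <- cfg$follow_beta
      p_follow <- stats::plogis(b[1] + b[2] * k + b[3] * A + b[4] * k * A)
      followed <- stats::runif(1) < p_follow
      move_extra(members, D * cos(dirs), D * sin(dirs), dur1)
      t2 <- t_cur - 1L
      hold_centroid(4L)
      if (!followed) {
        move_extra(members, rep(0, k), rep(0, k), dur1)
        t3_all <- rep(t_cur - 1L, k)
        pulls <- rep(FALSE, k)
        resp <- NA_real_
      } else {
        compromise <- (k == 2) && (theta < cfg$theta_c_deg * pi / 180)
        if (compromise) {
          resp <- phi
          pulls <- rep(TRUE, k)
        } else {
          sexes <- sim_metadata(cfg)$sex[members]
          mixed_two <- k == 2 && length(unique(sexes)) == 2
          p1 <- if (mixed_two) {
            if (sexes[cluster == 1][1] == "M") cfg$p_male_success
            else 1 - cfg$p_male_success
          } else stats::plogis(cfg$beta_major * (n1 - n2))
          chosen <- if (stats::runif(1) < p1) 1L else 2L
          resp <- phi + (if (chosen == 1L) theta / 2 else -theta / 2)
          pulls <- cluster == chosen
        }
        resp_n <- resp + rvonmises(1, 0, cfg$kappa_follower)
        u_r <- c(cos(resp_n), sin(resp_n))
        # followers advance 0.6 D along the response direction and then
        # continue the journey; successful (pulling) initiators hold their
        # outpost until the group reaches them, unsuccessful ones give up
        # at the decision point and chase the moving formation
        idx0 <- t_cur
        move_centroid(u_r, 0.6 * D)
        move_centroid(u_r, 1.4 * D)
        idx <- idx0:(t_cur - 1L)
        chase_frac <- seq_along(idx) / length(idx)
        for (a in seq_len(k)) {
          m <- members[a]
          x0 <- extra_x[m, idx0 - 1L]; y0 <- extra_y[m, idx0 - 1L]
          if (pulls[a]) {               # hold absolute position
            extra_x[m, idx] <- x0 - (Cx[idx] - Cx[idx0 - 1L])
            extra_y[m, idx] <- y0 - (Cy[idx] - Cy[idx0 - 1L])
          } else {                      # rejoin the moving formation
            extra_x[m, idx] <- x0 * (1 - chase_frac)
            extra_y[m, idx] <- y0 * (1 - chase_frac)
          }
          extra_x[m, t_cur:Tn] <- extra_x[m, t_cur - 1L]
          extra_y[m, t_cur:Tn] <- extra_y[m, t_cur - 1L]
        }
        t3_pull <- idx0 - 1L + ceiling(0.6 * D / v)   # end of the first leg
        t3_anchor <- t_cur - 1L                       # chaser rejoins here
        hold_centroid(4L)
        # pulling initiators catch up to the formation
        if (any(pulls)) {
          mem_p <- members[pulls]
          dur4 <- ceiling(max(sqrt((extra_x[mem_p, t_cur - 1L])^2 +
                                   (extra_y[mem_p, t_cur - 1L])^2)) /
                          cfg$catchup_speed)
          move_extra(mem_p, rep(0, sum(pulls)), rep(0, sum(pulls)),
                     max(dur4, 1L))
        }
        t3_all <- ifelse(pulls, t3_pull, t3_anchor)
      }
      rows <- expand.grid(mi = seq_len(k), fj = fol)
      truth[[e]] <- data.frame(episode = e,
                               initiator = ids[members[rows$mi]],
                               follower = ids[rows$fj],
                               outcome = ifelse(pulls[rows$mi], "pull", "anchor"),
                               t1 = t0 - 1L, t2 = t2, t3 = t3_all[rows$mi])
      eps[[e]] <- data.frame(episode = e, type = "multi", n_initiators = k,
                             t_start = t0, agreement = A, followed = followed,
                             theta_deg = theta * 180 / pi,
                             response_deg = if (followed) (resp * 180 / pi) %% 360 else NA_real_)
      if (!followed) truth[[e]]$outcome <- "anchor"
    }
    hold_centroid(cfg$quiescence)
  }
  Tn_used <- t_cur - 1L
  Cx <- Cx[seq_len(Tn_used)]; Cy <- Cy[seq_len(Tn_used)]
  extra_x <- extra_x[, seq_len(Tn_used), drop = FALSE]
  extra_y <- extra_y[, seq_len(Tn_used), drop = FALSE]
  # stationary AR(1) noise per agent: used both for within-formation
  # jitter and for GPS error, which at 1 Hz is strongly autocorrelated
  # (position error drifts over tens of seconds rather than resampling
  # white every fix)
  ar1 <- function(sd, phi) {
    m <- matrix(0, n, Tn_used)
    innov_sd <- sd * sqrt(1 - phi^2)
    m[, 1] <- stats::rnorm(n, 0, sd)
    for (t in 2:Tn_used) m[, t] <- phi * m[, t - 1] + stats::rnorm(n, 0, innov_sd)
    m
  }
  x <- sweep(extra_x, 2, Cx, `+`) + off_x + ar1(cfg$jitter_sd, 0.95)
  y <- sweep(extra_y, 2, Cy, `+`) + off_y + ar1(cfg$jitter_sd, 0.95)
  if (cfg$gps_noise_sd > 0) {
    # gps_noise_sd is the RMS of the 2D error vector per tag, so each
    # coordinate gets sd / sqrt(2); the ~50 s drift time constant matches
    # the slowly varying character of GPS error at 1 Hz
    x <- x + ar1(cfg$gps_noise_sd / sqrt(2), 0.98)
    y <- y + ar1(cfg$gps_noise_sd / sqrt(2), 0.98)
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(x)) < cfg$missing_rate, n, Tn_used)
    x[drop] <- NA_real_; y[drop] <- NA_real_
  }
  if (!is.null(cfg$dropout)) {
    for (r in seq_len(nrow(cfg$dropout))) {
      span <- seq(cfg$dropout$t_start[r], cfg$dropout$t_end[r])
      silent <- seq_len(cfg$dropout$n_ids[r])
      x[silent, span] <- NA_real_; y[silent, span] <- NA_real_
    }
  }
  if (cfg$n_outliers > 0) {
    cells <- which(!is.na(x))
    pick <- sample(cells, min(cfg$n_outliers, length(cells)))
    x[pick] <- cfg$arena / 2 + 5e5
    y[pick] <- cfg$arena / 2 + 5e5
  }
  times <- cfg$day_start + seq_len(Tn_used) - 1L
  grid <- trajectory_grid(ids, times, x, y)
  attr(grid, "metadata") <- sim_metadata(cfg)
  truth <- do.call(rbind, truth)
  # internal index i corresponds to epoch second day_start + i - 1
  truth$t1 <- truth$t1 + cfg$day_start - 1L
  truth$t2 <- truth$t2 + cfg$day_start - 1L
  truth$t3 <- truth$t3 + cfg$day_start - 1L
  episodes <- do.call(rbind, eps)
  episodes$t_start <- episodes$t_start + cfg$day_start - 1L
  list(grid = grid, truth = truth, episodes = episodes,
       metadata = sim_metadata(cfg), config = cfg)
}

#' Study area implied by a simulation (arena plus a 10% margin)
#' @param cfg a [sim_config()].
#' @return a [study_area()].
#' @export
sim_study_area <- function(cfg) {
  m <- 0.1 * cfg$arena
  study_area(xlim = c(-m, cfg$arena + m), ylim = c(-m, cfg$arena + m))
}

#' Write a simulated group as a Movebank-dialect CSV
#'
#' Planar positions are de-projected to lon/lat about the configured
#' origin so the full ingestion path (CSV, projection, gridding) is
#' exercised end-to-end.
#'
#' @param sim result of [simulate_group()].
#' @param path output CSV path.
#' @return the projection origin, invisibly.
#' @export
write_movebank_csv <- function(sim, path) {
  grid <- sim$grid
  present <- which(!is.na(grid$x), arr.ind = TRUE)
  ll <- unproject_xy(grid$x[present], grid$y[present],
                     sim$config$origin_lonlat)
  df <- data.frame(
    `individual-local-identifier` = grid$ids[present[, 1]],
    timestamp = format(as.POSIXct(grid$times[present[, 2]], tz = "UTC",
                                  origin = "1970-01-01"),
                       "%Y-%m-%d %H:%M:%S"),
    `location-long` = ll$lon, `location-lat` = ll$lat,
    check.names = FALSE)
  df <- df[order(df$`individual-local-identifier`, df$timestamp), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(sim$config$origin_lonlat)
}

# --- agonistic interactions ------------------------------------------------

#' Simulate agonistic interactions from a latent steep hierarchy
#'
#' Latent scores are evenly spaced with all males above all females (males
#' dominate every female in this system); for each sampled dyad the winner
#' is drawn by a logistic function of the latent score difference.
#'
#' @param cfg a [sim_config()] (uses ids, sexes, hierarchy steepness).
#' @param n_interactions total interactions to draw.
#' @param seed optional seed.
#' @return list with `interactions` (data.frame time, winner, loser) and
#'   `latent_rank` (named; 1 = most dominant).
#' @export
simulate_interactions <- function(cfg, n_interactions = 300, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  md <- sim_metadata(cfg)
  ids <- md$id
  n <- length(ids)
  latent <- seq(1, 0, length.out = n)        # males (first ids) on top
  rows <- lapply(seq_len(n_interactions), function(r) {
    pair <- sample.int(n, 2)
    p_first <- stats::plogis(cfg$hierarchy_steepness *
                             (latent[pair[1]] - latent[pair[2]]))
    w <- if (stats::runif(1) < p_first) pair else rev(pair)
    data.frame(time = r, winner = ids[w[1]], loser = ids[w[2]],
               stringsAsFactors = FALSE)
  })
  list(interactions = do.call(rbind, rows),
       latent_rank = setNames(seq_len(n), ids))
}

# --- event-level generators (planted statistical truth) --------------------

#' Simulate follower decisions at the event level
#'
#' Draws events with a number of simultaneous initiators and a directional
#' agreement, and resolves following from the planted logit
#' `b0 + b1 n + b2 A + b3 n A`. Used to validate the follower-decision
#' model at scale without re-running the trajectory pipeline.
#'
#' @param n_events number of events.
#' @param beta planted coefficients (defaults as in [sim_config()]).
#' @param n_followers follower identities to cluster on.
#' @param n_range candidate numbers of initiators.
#' @param seed optional seed.
#' @return data.frame with follower, n_initiators, agreement, success.
#' @export
sim_follow_events <- function(n_events, beta = c(0.6, -0.8, 0.5, 1.2),
                              n_followers = 15, n_range = 1:6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- sample(n_range, n_events, replace = TRUE)
  A <- stats::runif(n_events)
  eta <- beta[1] + beta[2] * k + beta[3] * A + beta[4] * k * A
  data.frame(follower = sample(sprintf("F%02d", seq_len(n_followers)),
                               n_events, replace = TRUE),
             n_initiators = k, agreement = A,
             success = stats::runif(n_events) < stats::plogis(eta))
}

#' Simulate two-initiator events in the symmetric frame
#'
#' Angular disagreement is uniform on (0, 180) degrees; below the planted
#' transition angle followers head to the bisector (compromise), above it
#' they pick one of the two initiator directions with equal probability
#' (choose), with von Mises noise either way.
#'
#' @param n_events number of events.
#' @param theta_c_deg planted transition angle (degrees).
#' @param kappa_follower follower-direction concentration.
#' @param seed optional seed.
#' @return data.frame with disagreement_deg, follower_rel (radians), and
#'   the planted regime label.
#' @export
sim_two_initiator_frame <- function(n_events, theta_c_deg = 100,
                                    kappa_follower = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- stats::runif(n_events, 0, 180)
  choose <- th >= theta_c_deg
  centre <- ifelse(choose,
                   ifelse(stats::runif(n_events) < 0.5, 1, -1) * th / 2,
                   0) * pi / 180
  data.frame(disagreement_deg = th,
             follower_rel = wrap_angle(centre +
                                       rvonmises(n_events, 0, kappa_follower)),
             regime_true = ifelse(choose, "choose", "compromise"))
}

#' Simulate two-cluster choose events under a planted majority rule
#'
#' @param n_events number of events.
#' @param beta_major planted logistic steepness of
#'   P(choose cluster 1) = logistic(beta (n1 - n2)).
#' @param n_total_range total pullers per event.
#' @param seed optional seed.
#' @return data.frame with n1, n2, chosen.
#' @export
sim_cluster_choice <- function(n_events, beta_major = log(4) / 4,
                               n_total_range = 3:12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tot <- sample(n_total_range, n_events, replace = TRUE)
  n1 <- vapply(tot, function(k) sample.int(k - 1L, 1), integer(1))
  n2 <- tot - n1
  p1 <- stats::plogis(beta_major * (n1 - n2))
  data.frame(n1 = n1, n2 = n2,
             chosen = ifelse(stats::runif(n_events) < p1, 1L, 2L))
}

#' Simulate mixed-sex two-puller outcomes
#' @param n_events number of events.
#' @param p_male probability the male is the successful puller.
#' @param seed optional seed.
#' @return logical vector (male won).
#' @export
sim_mixed_puller <- function(n_events, p_male = 0.55, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n_events) < p_male
}
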