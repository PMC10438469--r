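#' Configuration for the synthetic crypt simulator
#'
#' Defaults describe a single crypt imaged for 60 hours at one frame every
#' 12 minutes, starting from a couple of dozen stem cells, with commit-
#' then-divide differentiation: a committing cell changes type during its
#' own lifetime and its daughters inherit the new type, so end-point
#' sisters always share a type. Cycle-time means follow the per-type means
#' the analysis itself is designed to recover (enterocyte 12.5 h, TA
#' 14.1 h, stem 15.5 h). Commitment events are planted so that they are
#' identifiable from end-point staining: at most one daughter per fork is
#' scheduled to commit, and terminal-type commitments (and the divisions of
#' terminal clones) are only realised early enough for their markers to
#' mature before the movie ends.
#'
#' @param tube_radius_um,crypt_length_um,villus_length_um geometry of the
#'   cylindrical crypt-villus surface the cells live on.
#' @param frame_interval_h,movie_length_h imaging schedule.
#' @param n_initial_cells stem cells present at frame 0.
#' @param cycle_mean_h,cycle_cv per-type lognormal cycle-time parameters.
#' @param min_cycle_h lower truncation of cycle times.
#' @param p_commit per-division probability that one daughter of the fork
#'   is scheduled to commit, per mother type.
#' @param commit_targets per-type transition probabilities given a
#'   commitment (stem cells mostly yield TA plus rare direct secretory
#'   fates; TA yields absorptive and secretory terminal fates).
#' @param post_commit_divisions per-terminal-type probability vector over
#'   0, 1, 2, ... further divisions of each committed daughter.
#' @param maturation_delay_h time after the later of commitment and last
#'   division before a differentiated cell's markers become detectable.
#' @param advection_alpha_um_h axial speed gained per proliferative cell
#'   located below a cell (crypt-bottom proliferation pushes cells up).
#' @param motion_jitter_um isotropic per-frame positional jitter (SD).
#' @param sister_scatter_prob,sister_scatter_um per-type probability and
#'   magnitude of a one-off tangential displacement of one daughter at
#'   division (makes Paneth/IMPC sisters separate).
#' @param stain_jitter_sd_um,label_noise staining degradation applied to
#'   the emitted stain table (defaults 0: noiseless staining).
#' @param stain_intensity_pos,stain_intensity_neg intensity levels written
#'   for positive and negative marker calls.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(tube_radius_um = 12, crypt_length_um = 60,
                       villus_length_um = 80,
                       frame_interval_h = 0.2, movie_length_h = 60,
                       n_initial_cells = 24L,
                       initial_type_probs = c(STEM = 0.5, TA = 0.3,
                                              ENTEROCYTE = 0.1, GOBLET = 0.04,
                                              PANETH = 0.03, EEC = 0.02,
                                              IMPC = 0.01),
                       cycle_mean_h = c(STEM = 15.5, TA = 14.1,
                                        ENTEROCYTE = 12.5, EEC = 15,
                                        PANETH = 15, GOBLET = 15, IMPC = 15),
                       cycle_cv = 0.15, min_cycle_h = 4,
                       p_commit = c(STEM = 0.35, TA = 0.35),
                       commit_targets = list(
                         STEM = c(TA = 0.78, PANETH = 0.08, IMPC = 0.08, EEC = 0.06),
                         TA = c(ENTEROCYTE = 0.65, GOBLET = 0.22, EEC = 0.13)),
                       post_commit_divisions = list(
                         ENTEROCYTE = c(`0` = 0.1, `1` = 0.25, `2` = 0.3,
                                        `3` = 0.2, `4` = 0.1, `5` = 0.05),
                         PANETH = c(`0` = 0.55, `1` = 0.35, `2` = 0.1),
                         GOBLET = c(`0` = 0.55, `1` = 0.35, `2` = 0.1),
                         EEC = c(`0` = 0.6, `1` = 0.35, `2` = 0.05),
                         IMPC = c(`0` = 0.45, `1` = 0.4, `2` = 0.15)),
                       maturation_delay_h = 20,
                       advection_alpha_um_h = 0.012,
                       motion_jitter_um = 0.25,
                       sister_scatter_prob = c(PANETH = 0.8, IMPC = 0.6),
                       sister_scatter_um = c(PANETH = 8, IMPC = 6),
                       stain_jitter_sd_um = 0, label_noise = 0,
                       stain_intensity_pos = 100, stain_intensity_neg = 2) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(p_commit) >= 0), all(unlist(p_commit) <= 1),
            all(unlist(cfg$sister_scatter_prob) >= 0),
            movie_length_h > 0, frame_interval_h > 0)
  for (t in names(cfg$commit_targets)) {
    cfg$commit_targets[[t]] <- cfg$commit_targets[[t]] / sum(cfg$commit_targets[[t]])
  }
  class(cfg) <- "sim_config"
  cfg
}

type_markers <- function(type) {
  switch(type,
         STEM = "Olfm4", EEC = "Cga", ENTEROCYTE = c("Aldob", "KRT20"),
         PANETH = c("WGA", "Lyz"), GOBLET = c("WGA", "KRT20"),
         IMPC = "WGA", TA = character(0), character(0))
}

rcycle <- function(n, mean_h, cv, min_h) {
  sdlog <- sqrt(log(1 + cv^2))
  mlog <- log(mean_h) - sdlog^2 / 2
  pmax(stats::rlnorm(n, mlog, sdlog), min_h)
}

#' Simulate a crypt-villus tracking dataset with ground truth
#'
#' Generates a lineage forest, an end-point staining table, per-frame axis
#' annotations and the ground truth (true per-track type intervals,
#' planted commitment events, sister-scatter flags). Cells live on the
#' surface of a cylinder whose axis is the crypt-villus axis; motion is
#' advection proportional to the number of proliferative cells below plus
#' isotropic jitter. See [sim_config()] for the differentiation model.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; recorded in the output.
#' @return list of class `sim_dataset`: `forest`, `stain`, `axis`
#'   (annotation data frame), `truth`, `config`, `seed`.
#' @export
simulate_crypt <- function(config = sim_config(), seed = 1L) {
  cfg <- config
  dt <- cfg$frame_interval_h
  Tend <- cfg$movie_length_h
  Fend <- as.integer(round(Tend / dt))
  delay <- cfg$maturation_delay_h
  term_deadline <- Tend - delay - dt     # latest birth of a differentiated cell
  with_seed(seed, {
    cap <- 1e5L
    cells <- list()
    queue <- integer(0)
    new_cell <- function(parent, birth_t, first_frame, type, remaining,
                         pending, scatter) {
      id <- length(cells) + 1L
      if (id > cap) stop("configuration produces more than 1e5 cells; shorten the movie or reduce rates")
      cells[[id]] <<- list(id = id, parent = parent, birth_t = birth_t,
                           first_frame = first_frame, type = type,
                           remaining = remaining, pending = pending,
                           scatter = scatter, commit_t = NA_real_,
                           commit_from = NA_character_, commit_to = NA_character_,
                           div_t = NA_real_, last_frame = NA_integer_,
                           daughters = NULL)
      queue <<- c(queue, id)
      id
    }
    # mixed initial population: the organoid already contains proliferative
    # and differentiated cells when imaging starts
    init_types <- sample(names(cfg$initial_type_probs), cfg$n_initial_cells,
                         replace = TRUE, prob = cfg$initial_type_probs)
    for (i in seq_len(cfg$n_initial_cells)) {
      ty <- init_types[i]
      rem <- if (ty %in% c("STEM", "TA")) Inf else 0
      new_cell(NA_integer_, 0, 0L, ty, rem, NA_character_, FALSE)
    }
    qi <- 0L
    while (qi < length(queue)) {
      qi <- qi + 1L
      id <- queue[[qi]]
      cl <- cells[[id]]
      L <- rcycle(1L, cfg$cycle_mean_h[[cl$type]], cfg$cycle_cv, cfg$min_cycle_h)
      td <- if (is.na(cl$parent)) cl$birth_t + stats::runif(1) * L else cl$birth_t + L
      divides_in_movie <- floor(td / dt) + 1L <= Fend
      # realise a scheduled commitment: only in cells that go on to divide
      # (so end-point type always equals birth type and sisters match), and
      # for terminal fates only early enough for the clone to mature
      commit_type <- NA_character_
      if (!is.na(cl$pending) && divides_in_movie) {
        terminal <- !(cl$pending %in% c("STEM", "TA"))
        if (!terminal || td <= term_deadline) commit_type <- cl$pending
      }
      if (!is.na(commit_type)) {
        cl$commit_t <- stats::runif(1, cl$birth_t, td)
        cl$commit_from <- cl$type
        cl$commit_to <- commit_type
        cl$type_end <- commit_type
      } else {
        cl$type_end <- cl$type
      }
      etype <- cl$type_end
      eterminal <- !(etype %in% c("STEM", "TA"))
      committed_now <- !is.na(commit_type)
      # the commitment division itself always happens; an established
      # terminal cell divides only while its division budget lasts and
      # while the resulting daughters can still mature
      can_divide <- divides_in_movie &&
        (committed_now || !eterminal ||
           (cl$remaining > 0 && td <= term_deadline))
      if (can_divide) {
        cl$div_t <- td
        cl$last_frame <- as.integer(floor(td / dt))
        rem_d <- if (!eterminal) {
          Inf
        } else if (committed_now) {
          pmf <- cfg$post_commit_divisions[[etype]]
          sample(as.integer(names(pmf)), 1L, prob = pmf)
        } else {
          cl$remaining - 1L
        }
        # schedule at most one daughter of this fork to commit
        pend <- c(NA_character_, NA_character_)
        if (etype %in% names(cfg$p_commit) &&
            stats::runif(1) < cfg$p_commit[[etype]]) {
          tgt <- cfg$commit_targets[[etype]]
          pend[sample(2L, 1L)] <- sample(names(tgt), 1L, prob = tgt)
        }
        scat <- c(FALSE, FALSE)
        if (eterminal && etype %in% names(cfg$sister_scatter_prob) &&
            stats::runif(1) < cfg$sister_scatter_prob[[etype]]) {
          scat[sample(2L, 1L)] <- TRUE
        }
        da <- new_cell(id, td, cl$last_frame + 1L, etype, rem_d, pend[1L], scat[1L])
        db <- new_cell(id, td, cl$last_frame + 1L, etype, rem_d, pend[2L], scat[2L])
        cl$daughters <- c(da, db)
      } else {
        cl$last_frame <- Fend
      }
      cells[[id]] <- cl
    }

    n <- length(cells)
    ids <- sprintf("c%04d", seq_len(n))
    first <- vapply(cells, `[[`, integer(1), "first_frame")
    last <- vapply(cells, `[[`, integer(1), "last_frame")
    parent_i <- vapply(cells, function(cl) as.integer(cl$parent), integer(1))

    ## positions: frame loop over the tube surface
    theta <- s_ax <- rep(NA_real_, n)
    npts <- last - first + 1L
    off <- cumsum(c(0L, npts[-n]))
    px <- py <- pz <- numeric(sum(npts))
    prolif_end <- vapply(cells, function(cl) cl$type_end %in% c("STEM", "TA"), logical(1))
    Lmax <- cfg$crypt_length_um + cfg$villus_length_um
    R <- cfg$tube_radius_um
    for (f in 0:Fend) {
      born <- which(first == f)
      for (id in born) {
        p <- parent_i[id]
        if (is.na(p)) {
          theta[id] <- stats::runif(1, 0, 2 * pi)
          Lc <- cfg$crypt_length_um
          s_ax[id] <- switch(cells[[id]]$type,
                             STEM = stats::runif(1, 0, 0.4 * Lc),
                             PANETH = stats::runif(1, 0, 0.3 * Lc),
                             TA = stats::runif(1, 0.3 * Lc, 0.7 * Lc),
                             IMPC = stats::runif(1, 0.2 * Lc, 0.8 * Lc),
                             EEC = stats::runif(1, 0.3 * Lc, Lc + 0.3 * cfg$villus_length_um),
                             stats::runif(1, 0.8 * Lc, Lc + 0.6 * cfg$villus_length_um))
        } else {
          sgn <- if (cells[[p]]$daughters[1L] == id) -1 else 1
          theta[id] <- theta[p] + sgn * stats::runif(1, 0.5, 1.5) / R
          s_ax[id] <- s_ax[p] + sgn * stats::runif(1, 0.2, 0.8)
          if (cells[[id]]$scatter) {
            theta[id] <- theta[id] +
              sample(c(-1, 1), 1L) * cfg$sister_scatter_um[[cells[[id]]$type]] / R
          }
        }
      }
      alive <- which(first <= f & last >= f)
      # advection from proliferative cells below, then isotropic jitter
      sp <- sort(s_ax[alive[prolif_end[alive]]])
      v <- cfg$advection_alpha_um_h * findInterval(s_ax[alive], sp)
      s_ax[alive] <- s_ax[alive] + v * dt +
        stats::rnorm(length(alive), 0, cfg$motion_jitter_um)
      theta[alive] <- theta[alive] +
        stats::rnorm(length(alive), 0, cfg$motion_jitter_um / R)
      s_ax[alive] <- abs(s_ax[alive])
      s_ax[alive] <- pmin(s_ax[alive], 2 * Lmax - s_ax[alive])
      k <- off[alive] + (f - first[alive]) + 1L
      px[k] <- R * cos(theta[alive])
      py[k] <- R * sin(theta[alive])
      pz[k] <- s_ax[alive]
    }
    points <- data.frame(
      track_id = rep(ids, npts),
      frame = unlist(lapply(seq_len(n), function(i) first[i]:last[i])),
      x = px, y = py, z = pz)

    links <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (is.null(cells[[i]]$daughters)) return(NULL)
      data.frame(child_id = ids[cells[[i]]$daughters], parent_id = ids[i])
    }))
    forest <- lineage_forest(points, links, movie_end_frame = Fend,
                             frame_interval_h = dt)

    ## ground truth
    has_commit <- !vapply(cells, function(cl) is.na(cl$commit_t), logical(1))
    truth_trans <- data.frame(
      track_id = ids[has_commit],
      t_h = vapply(cells[has_commit], `[[`, numeric(1), "commit_t"),
      frame = as.integer(ceiling(vapply(cells[has_commit], `[[`, numeric(1), "commit_t") / dt)),
      from_type = vapply(cells[has_commit], `[[`, character(1), "commit_from"),
      to_type = vapply(cells[has_commit], `[[`, character(1), "commit_to"))
    rownames(truth_trans) <- NULL
    ivl <- lapply(seq_len(n), function(i) {
      cl <- cells[[i]]
      if (!is.na(cl$commit_t)) {
        cf <- min(max(as.integer(ceiling(cl$commit_t / dt)), first[i]), last[i])
        if (cf > first[i]) {
          return(data.frame(track_id = ids[i],
                            start_frame = c(first[i], cf),
                            end_frame = c(cf - 1L, last[i]),
                            type = c(cl$type, cl$commit_to)))
        }
        return(data.frame(track_id = ids[i], start_frame = first[i],
                          end_frame = last[i], type = cl$commit_to))
      }
      data.frame(track_id = ids[i], start_frame = first[i],
                 end_frame = last[i], type = cl$type)
    })
    truth_intervals <- do.call(rbind, ivl)
    scatter_flags <- data.frame(track_id = ids,
                                scattered = vapply(cells, `[[`, logical(1), "scatter"),
                                type = vapply(cells, `[[`, character(1), "type"))

    ## end-point staining table
    ep <- which(last == Fend & vapply(cells, function(cl) is.null(cl$daughters), logical(1)))
    mk <- markers()
    stain_int <- matrix(cfg$stain_intensity_neg, length(ep), length(mk),
                        dimnames = list(NULL, mk))
    ep_type <- vapply(cells[ep], `[[`, character(1), "type_end")
    for (j in seq_along(ep)) {
      cl <- cells[[ep[j]]]
      ty <- cl$type_end
      if (!(ty %in% c("STEM", "TA"))) {
        # markers visible only after maturation since the later of
        # commitment and last division (= this cell's birth)
        clock <- max(cl$birth_t, if (!is.na(cl$commit_t)) cl$commit_t else -Inf)
        if (Tend - clock <= delay) ty <- "TA"   # immature: appears unstained
      }
      stain_int[j, type_markers(ty)] <- cfg$stain_intensity_pos
    }
    kend <- off[ep] + (Fend - first[ep]) + 1L
    stain <- data.frame(stain_cell_id = sprintf("s%04d", seq_along(ep)),
                        x = px[kend], y = py[kend], z = pz[kend])
    stain <- cbind(stain, as.data.frame(stain_int))
    if (cfg$stain_jitter_sd_um > 0) {
      stain$x <- stain$x + stats::rnorm(nrow(stain), 0, cfg$stain_jitter_sd_um)
      stain$y <- stain$y + stats::rnorm(nrow(stain), 0, cfg$stain_jitter_sd_um)
      stain$z <- stain$z + stats::rnorm(nrow(stain), 0, cfg$stain_jitter_sd_um)
    }

    ## axis annotations: centerline of the tube, bottom first, neck at the
    ## crypt/villus junction
    zs <- c(0, cfg$crypt_length_um / 2, cfg$crypt_length_um, Lmax)
    axis <- do.call(rbind, lapply(0:Fend, function(f) {
      data.frame(frame = f, point_index = c(seq_along(zs), length(zs) + 1L),
                 x = 0, y = 0, z = c(zs, cfg$crypt_length_um),
                 is_neck = c(rep(0L, length(zs)), 1L))
    }))

    structure(list(forest = forest, stain = stain, axis = axis,
                   truth = list(transitions = truth_trans,
                                intervals = truth_intervals,
                                scatter = scatter_flags,
                                endpoint_types = stats::setNames(ep_type, ids[ep])),
                   config = cfg, seed = seed),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic crypt dataset (seed ", x$seed, "):\n", sep = "")
  print(x$forest)
  cat("  ", nrow(x$stain), " stained end-point cells, ",
      nrow(x$truth$transitions), " planted commitment events\n", sep = "")
  invisible(x)
}

#' Degrade a synthetic dataset
#'
#' Adds staining position jitter, flips marker calls at a given rate, and
#' truncates random tracks (marking them lost and dropping their
#' descendants). Marker flips use common random numbers: with the same
#' seed, the cells flipped at rate r are a subset of those flipped at any
#' r' > r, so recovery curves over a noise sweep are directly comparable.
#'
#' @param dataset a `sim_dataset`.
#' @param stain_jitter_sd_um SD of Gaussian jitter added to stain
#'   positions.
#' @param label_noise per-(cell, marker) flip probability in `[0, 1]`.
#' @param track_loss_rate probability that a non-root track is truncated.
#' @param seed RNG seed.
#' @return a degraded `sim_dataset`.
#' @export
degrade_dataset <- function(dataset, stain_jitter_sd_um = 0, label_noise = 0,
                            track_loss_rate = 0, seed = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"),
            label_noise >= 0, label_noise <= 1,
            track_loss_rate >= 0, track_loss_rate <= 1,
            stain_jitter_sd_um >= 0)
  ds <- dataset
  cfg <- ds$config
  mk <- markers()
  with_seed(seed, {
    U <- matrix(stats::runif(nrow(ds$stain) * length(mk)), nrow(ds$stain))
    if (label_noise > 0) {
      flips <- U < label_noise
      M <- as.matrix(ds$stain[, mk])
      M[flips] <- cfg$stain_intensity_pos + cfg$stain_intensity_neg - M[flips]
      ds$stain[, mk] <- M
    }
    if (stain_jitter_sd_um > 0) {
      ds$stain$x <- ds$stain$x + stats::rnorm(nrow(ds$stain), 0, stain_jitter_sd_um)
      ds$stain$y <- ds$stain$y + stats::rnorm(nrow(ds$stain), 0, stain_jitter_sd_um)
      ds$stain$z <- ds$stain$z + stats::rnorm(nrow(ds$stain), 0, stain_jitter_sd_um)
    }
    if (track_loss_rate > 0) {
      forest <- ds$forest
      tr <- forest$tracks
      nonroot <- tr$track_id[!is.na(tr$parent)]
      lose <- nonroot[stats::runif(length(nonroot)) < track_loss_rate]
      if (length(lose)) {
        # descendants of a truncated track vanish; a lost track nested under
        # another lost track is simply dropped with the rest of the subtree
        drop <- unique(unlist(lapply(lose, function(id) {
          setdiff(subtree_ids(tr, id), id)
        })))
        lose <- setdiff(lose, drop)
        keep_tr <- setdiff(tr$track_id, union(drop, lose))
        cut_at <- stats::setNames(
          vapply(lose, function(id) {
            fr <- tr[id, "first_frame"]:max(tr[id, "first_frame"],
                                            tr[id, "last_frame"] - 1L)
            fr[sample.int(length(fr), 1L)]
          }, numeric(1)), lose)
        pts <- forest$points
        keep_row <- pts$track_id %in% keep_tr |
          (pts$track_id %in% lose & pts$frame <= cut_at[pts$track_id])
        pts <- pts[keep_row, , drop = FALSE]
        present <- union(keep_tr, lose)
        links <- data.frame(child_id = c(tr$daughter1, tr$daughter2),
                            parent_id = c(tr$track_id, tr$track_id))
        links <- links[!is.na(links$child_id) &
                         links$child_id %in% present &
                         links$parent_id %in% present, , drop = FALSE]
        # truncated tracks lose their daughters
        links <- links[!(links$parent_id %in% lose), , drop = FALSE]
        # a fork that lost one daughter track entirely loses the other link too
        nk <- table(links$parent_id)
        links <- links[links$parent_id %in% names(nk)[nk == 2L], , drop = FALSE]
        er <- tr[tr$end_reason == "death" & tr$track_id %in% present,
                 c("track_id", "end_reason")]
        ds$forest <- lineage_forest(pts, links,
                                    movie_end_frame = forest$movie_end_frame,
                                    frame_interval_h = forest$frame_interval_h,
                                    end_reasons = er)
        ds$truth$intervals <- ds$truth$intervals[ds$truth$intervals$track_id %in% present, ]
        ds$truth$transitions <- ds$truth$transitions[ds$truth$transitions$track_id %in% present, ]
      }
    }
  })
  ds
}
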