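## Synthetic 4D track generator. Motion archetypes: LM = tight confined walk,
## MT = wider confined walk, LD = persistent (directed) random walk.
## Interaction archetypes: PC = isolated + LM motion, IC = coupled pairs held
## within contact range, AC = mobile (MT/LD) and isolated.

#' Default archetype parameters for the synthetic generator
#'
#' Motion scales per track type (micrometers per frame, confinement radii,
#' directional persistence), measurement jitter, pair-coupling parameters
#' and per-marker intensity models. The \code{overlap} knob blends each
#' class's motion parameters toward the across-class mean and inflates the
#' measurement jitter, producing progressively less separable classes
#' (0 = fully separated defaults, values near 1 = nearly indistinguishable).
#'
#' @param overlap class-overlap level in [0, 1) (default 0).
#' @return Named list of generator parameters.
#' @export
archetypeParams <- function(overlap = 0) {
  if (length(overlap) != 1L || !is.finite(overlap) || overlap < 0 ||
      overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)
  step <- c(LM = 0.3, MT = 1.2, LD = 3.0)
  conf <- c(LM = 2, MT = 8)
  blend <- function(v) (1 - overlap) * v + overlap * mean(v)
  list(
    stepUm = blend(step),
    confinementRadiusUm = blend(conf),
    persistence = (1 - overlap) * 0.95,
    stepCv = 0.3,                      # relative sd of step lengths
    jitterUm = 0.1 + 2 * overlap,     # centroid measurement noise (sd)
    couplingThresholdUm = 6,           # IC spring engages beyond this
    couplingPull = 0.9,                # fraction of excess separation removed
    pairOffsetUm = 5,                  # initial partner separation
    contactDwellFraction = 0.8,        # fraction of frames with coupling on
    isolationUm = 12,                  # min initial nearest-neighbor distance
    intensity = list(
      CD20 = c(mean = 120, trackSd = 15, pointSd = 5),
      PD1  = c(mean = 90,  trackSd = 12, pointSd = 5)))
}

.randDir <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

.reflectSphere <- function(p, center, radius) {
  d <- sqrt(sum((p - center)^2))
  if (d <= radius || d < 1e-12) return(p)
  excess <- d - radius
  center + (p - center) / d * max(radius - excess, 0)
}

.clampBox <- function(xyz, box) {
  if (is.null(box)) return(xyz)
  for (k in 1:3) xyz[, k] <- pmin(pmax(xyz[, k], 0), box[k])
  xyz
}

.reflectBox <- function(pos, dir, box) {
  ## specular reflection at the imaging-volume walls; preserves step length
  for (k in 1:3) {
    if (pos[k] < 0) {
      pos[k] <- -pos[k]
      if (!is.null(dir)) dir[k] <- -dir[k]
    } else if (pos[k] > box[k]) {
      pos[k] <- 2 * box[k] - pos[k]
      if (!is.null(dir)) dir[k] <- -dir[k]
    }
    pos[k] <- min(max(pos[k], 0), box[k])  # guard huge overshoots
  }
  list(pos = pos, dir = dir)
}

.stepLength <- function(par, type) {
  abs(stats::rnorm(1L, par$stepUm[[type]], par$stepCv * par$stepUm[[type]]))
}

.advance <- function(pos, type, par, state, box = NULL) {
  ## one motion-model step; state carries the confinement center (LM/MT)
  ## or the current heading (LD); walls reflect specularly
  if (type %in% c("LM", "MT")) {
    p <- pos + .randDir() * .stepLength(par, type)
    p <- .reflectSphere(p, state$center, par$confinementRadiusUm[[type]])
    if (!is.null(box)) p <- .reflectBox(p, NULL, box)$pos
    list(pos = p, state = state)
  } else {
    dir <- par$persistence * state$dir + (1 - par$persistence) * .randDir()
    n <- sqrt(sum(dir^2))
    dir <- if (n > 1e-12) dir / n else .randDir()
    p <- pos + dir * .stepLength(par, type)
    if (!is.null(box)) {
      ref <- .reflectBox(p, dir, box)
      p <- ref$pos; dir <- ref$dir
    }
    list(pos = p, state = list(dir = dir))
  }
}

.initState <- function(type, start) {
  if (type %in% c("LM", "MT")) list(center = start) else list(dir = .randDir())
}

.simPath <- function(type, par, nFrames, start, box = NULL) {
  xyz <- matrix(NA_real_, nFrames, 3L)
  xyz[1L, ] <- start
  state <- .initState(type, start)
  pos <- start
  for (t in seq_len(nFrames - 1L)) {
    stepped <- .advance(pos, type, par, state, box)
    pos <- stepped$pos; state <- stepped$state
    xyz[t + 1L, ] <- pos
  }
  xyz
}

.simCoupledPair <- function(type, par, nFrames, anchor, box) {
  ## partner A moves freely; partner B moves by its own model plus a spring
  ## pull toward A whenever separation exceeds the coupling threshold,
  ## during the first contactDwellFraction of frames
  off <- .randDir() * par$pairOffsetUm
  a <- matrix(NA_real_, nFrames, 3L); b <- matrix(NA_real_, nFrames, 3L)
  a[1L, ] <- anchor; b[1L, ] <- anchor + off
  stateA <- .initState(type, a[1L, ]); stateB <- .initState(type, b[1L, ])
  posA <- a[1L, ]; posB <- b[1L, ]
  onUntil <- ceiling(par$contactDwellFraction * nFrames)
  for (t in seq_len(nFrames - 1L)) {
    sa <- .advance(posA, type, par, stateA, box)
    posA <- sa$pos; stateA <- sa$state
    sb <- .advance(posB, type, par, stateB, box)
    posB <- sb$pos; stateB <- sb$state
    if (t + 1L <= onUntil) {
      gap <- posB - posA
      d <- sqrt(sum(gap^2))
      if (d > par$couplingThresholdUm)
        posB <- posA + gap / d *
          (d - par$couplingPull * (d - par$couplingThresholdUm))
      if (type %in% c("LM", "MT"))   # B's confinement sphere follows A
        stateB$center <- posA + off
      if (!is.null(box)) posB <- pmin(pmax(posB, 0), box)
    }
    a[t + 1L, ] <- posA; b[t + 1L, ] <- posB
  }
  list(a = a, b = b)
}

.trackDf <- function(id, xyz, par, marker, frameIntervalMin, box,
                     caseId, movieId, diagnosis, tracktype, actiontype) {
  n <- nrow(xyz)
  xyz <- xyz + matrix(stats::rnorm(3L * n, 0, par$jitterUm), n, 3L)
  xyz <- .clampBox(xyz, box)
  ipar <- par$intensity[[marker]]
  if (is.null(ipar)) ipar <- c(mean = 100, trackSd = 10, pointSd = 5)
  base <- max(stats::rnorm(1L, ipar[["mean"]], ipar[["trackSd"]]), 1)
  intensity <- pmax(base + stats::rnorm(n, 0, ipar[["pointSd"]]), 0)
  data.frame(track_id = id, frame = seq_len(n) - 1L,
             time_min = (seq_len(n) - 1L) * frameIntervalMin,
             x_um = xyz[, 1L], y_um = xyz[, 2L], z_um = xyz[, 3L],
             intensity = intensity, marker = marker,
             case_id = caseId, movie_id = movieId, diagnosis = diagnosis,
             tracktype = tracktype, actiontype = actiontype,
             stringsAsFactors = FALSE)
}

#' Simulate a single track of a given motion archetype
#'
#' Generates one synthetic track: LM as a tight confined random walk
#' (reflective sphere, default radius 2 um, step 0.3 um/frame), MT as a
#' wider confined walk (radius 8 um, step 1.2 um/frame), LD as a persistent
#' random walk (step 3 um/frame at persistence 0.95, i.e. a mean speed of
#' about 6 um/min at the default 0.5-min frame interval). Setting
#' \code{persistence = 0} via \code{params} reduces LD to an unbiased random
#' walk.
#'
#' @param trackType "LM", "MT" or "LD".
#' @param nFrames number of frames (>= 2).
#' @param params generator parameters from \code{\link{archetypeParams}}.
#' @param frameIntervalMin sampling step in minutes (default 0.5).
#' @param seed optional integer seed (NULL: use the current RNG stream).
#' @param start starting position (micrometers, default origin).
#' @param marker staining marker (default "CD20").
#' @return A one-track \linkS4class{TrackSet}.
#' @export
simulateTrack <- function(trackType = c("LM", "MT", "LD"), nFrames = 60L,
                          params = archetypeParams(),
                          frameIntervalMin = 0.5, seed = NULL,
                          start = c(0, 0, 0), marker = "CD20") {
  trackType <- match.arg(trackType)
  nFrames <- as.integer(nFrames)
  if (nFrames < 2L) stop("nFrames must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  xyz <- .simPath(trackType, params, nFrames, start)
  df <- .trackDf("sim_t001", xyz, params, marker, frameIntervalMin,
                 box = NULL, caseId = "simcase", movieId = "simmovie",
                 diagnosis = "synthetic", tracktype = trackType,
                 actiontype = if (trackType == "LM") "PC" else "AC")
  TrackSet(df, frameIntervalMin = frameIntervalMin)
}

#' Simulate pure Brownian reference tracks
#'
#' Generates tracks of 3D Brownian motion with diffusion coefficient
#' \code{D} (um^2/min): per-frame displacements are independent Gaussians
#' with per-axis variance 2 D dt, so the ensemble MSD is 6 D tau. Used as a
#' closed-form calibration reference for the MSD machinery.
#'
#' @param nTracks number of tracks.
#' @param nFrames frames per track.
#' @param D diffusion coefficient in um^2/min.
#' @param frameIntervalMin sampling step in minutes.
#' @param seed optional integer seed.
#' @return A \linkS4class{TrackSet}.
#' @export
simulateBrownianTracks <- function(nTracks = 200L, nFrames = 100L, D = 1,
                                   frameIntervalMin = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sdStep <- sqrt(2 * D * frameIntervalMin)
  dfs <- lapply(seq_len(nTracks), function(i) {
    steps <- matrix(stats::rnorm(3L * (nFrames - 1L), 0, sdStep),
                    nFrames - 1L, 3L)
    xyz <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    data.frame(track_id = sprintf("bm_t%04d", i),
               frame = seq_len(nFrames) - 1L,
               time_min = (seq_len(nFrames) - 1L) * frameIntervalMin,
               x_um = xyz[, 1L], y_um = xyz[, 2L], z_um = xyz[, 3L],
               intensity = 100, marker = "CD20", stringsAsFactors = FALSE)
  })
  TrackSet(do.call(rbind, dfs), frameIntervalMin = frameIntervalMin)
}

#' Scenario configuration for a synthetic movie
#'
#' Bundles everything \code{\link{simulateMovie}} needs: the number of
#' tracks per (marker, track type, action type) combination, movie length
#' and sampling, the imaging volume, archetype parameters, seed and cohort
#' labels. PC is only compatible with LM motion (passive means nearly
#' stationary); IC combinations need an even count (cells are placed as
#' coupled pairs). \code{nFrames * frameIntervalMin} defaults to 30 min so
#' all tracks survive the 5-minute duration filter.
#'
#' @param combos data.frame (marker, track_type, action_type, n).
#' @param nFrames frames per movie (default 60).
#' @param frameIntervalMin sampling step in minutes (default 0.5).
#' @param boxUm imaging volume in micrometers (default c(200, 200, 60)).
#' @param seed integer seed.
#' @param diagnosis,caseId,movieId cohort labels.
#' @param overlap class-overlap level passed to
#'   \code{\link{archetypeParams}}.
#' @param params generator parameters (default
#'   \code{archetypeParams(overlap)}).
#' @return A list of class "ScenarioConfig".
#' @export
scenarioConfig <- function(combos = defaultCombos(), nFrames = 60L,
                           frameIntervalMin = 0.5,
                           boxUm = c(200, 200, 60), seed = 1L,
                           diagnosis = "unspecified", caseId = "case1",
                           movieId = "movie1", overlap = 0,
                           params = archetypeParams(overlap)) {
  stopifnot(is.data.frame(combos),
            all(c("marker", "track_type", "action_type", "n")
                %in% names(combos)))
  bad <- !(combos$track_type %in% .TRACK_TYPES) |
         !(combos$action_type %in% .ACTION_TYPES)
  if (any(bad)) stop("unknown track/action type in combos", call. = FALSE)
  if (any(combos$action_type == "PC" & combos$track_type != "LM"))
    stop("PC (passive) requires LM motion", call. = FALSE)
  if (any(combos$action_type == "IC" & combos$n %% 2L != 0L))
    stop("IC combinations need an even n (cells are paired)", call. = FALSE)
  if (any(combos$n < 0)) stop("negative track count", call. = FALSE)
  if (length(boxUm) != 3L || any(boxUm <= 0))
    stop("boxUm must be 3 positive extents", call. = FALSE)
  structure(list(combos = combos, nFrames = as.integer(nFrames),
                 frameIntervalMin = frameIntervalMin, boxUm = boxUm,
                 seed = as.integer(seed), diagnosis = diagnosis,
                 caseId = caseId, movieId = movieId, params = params),
            class = "ScenarioConfig")
}

#' Default per-movie archetype mix
#'
#' The default mix per marker and movie: 50 tracks spread over the
#' compatible (track type, action type) combinations so that, over the
#' default six-movie cohort, track types are close to balanced.
#'
#' @param markers markers to include (default CD20 and PD1).
#' @param scale integer multiplier on all counts.
#' @return data.frame (marker, track_type, action_type, n).
#' @export
defaultCombos <- function(markers = c("CD20", "PD1"), scale = 1L) {
  base <- data.frame(
    track_type  = c("LM", "LM", "MT", "MT", "LD", "LD"),
    action_type = c("PC", "IC", "IC", "AC", "IC", "AC"),
    n           = c(10L,  8L,   8L,   9L,   4L,   11L))
  out <- do.call(rbind, lapply(markers, function(m)
    cbind(data.frame(marker = m, stringsAsFactors = FALSE), base)))
  out$n <- out$n * as.integer(scale)
  rownames(out) <- NULL
  out
}

.placeAnchors <- function(nUnits, box, minDist, margin = 10) {
  lo <- pmin(margin, box / 4)
  hi <- box - lo
  anchors <- matrix(NA_real_, nUnits, 3L)
  for (i in seq_len(nUnits)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      cand <- lo + stats::runif(3) * (hi - lo)
      if (i == 1L ||
          min(sqrt(rowSums((anchors[seq_len(i - 1L), , drop = FALSE] -
                            matrix(cand, i - 1L, 3L, byrow = TRUE))^2))) >
          minDist) {
        anchors[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("imaging volume too small for the requested isolation distance",
           call. = FALSE)
  }
  anchors
}

#' Simulate one labeled synthetic movie
#'
#' Generates a full movie of tracks per the scenario: PC cells are placed
#' isolated (initial nearest-neighbor distance above the isolation
#' threshold) with LM motion; IC cells are placed as coupled pairs whose
#' partner is spring-attracted whenever separation exceeds the coupling
#' threshold, keeping the pair within contact range for the configured
#' dwell fraction of frames; AC cells are mobile (MT or LD motion) and
#' placed isolated. Ground-truth labels are carried both in the TrackSet's
#' label columns and in a separate label table. Identical seeds give
#' identical output.
#'
#' @param scenario a \code{\link{scenarioConfig}}.
#' @return list with elements \code{tracks} (\linkS4class{TrackSet}) and
#'   \code{labels} (data.frame track_id, track_type, action_type).
#' @export
simulateMovie <- function(scenario) {
  stopifnot(inherits(scenario, "ScenarioConfig"))
  set.seed(scenario$seed)
  cmb <- scenario$combos
  cmb <- cmb[cmb$n > 0L, , drop = FALSE]
  par <- scenario$params
  box <- scenario$boxUm
  nF <- scenario$nFrames

  ## units: one anchor per isolated cell, one per IC pair
  units <- do.call(rbind, lapply(seq_len(nrow(cmb)), function(i) {
    r <- cmb[i, ]
    if (r$action_type == "IC") {
      k <- r$n %/% 2L
      if (!k) return(NULL)
      data.frame(marker = r$marker, track_type = r$track_type,
                 action_type = r$action_type, size = rep(2L, k))
    } else {
      data.frame(marker = r$marker, track_type = r$track_type,
                 action_type = r$action_type, size = rep(1L, r$n))
    }
  }))
  if (is.null(units) || !nrow(units)) {
    empty <- TrackSet(
      data.frame(track_id = character(0), frame = integer(0),
                 time_min = numeric(0), x_um = numeric(0), y_um = numeric(0),
                 z_um = numeric(0), intensity = numeric(0),
                 marker = character(0), tracktype = character(0),
                 actiontype = character(0)),
      frameIntervalMin = scenario$frameIntervalMin)
    return(list(tracks = empty,
                labels = data.frame(track_id = character(0),
                                    track_type = character(0),
                                    action_type = character(0))))
  }
  anchors <- .placeAnchors(nrow(units), box, par$isolationUm)

  dfs <- vector("list", sum(units$size))
  idn <- 0L
  nextId <- function() {
    idn <<- idn + 1L
    sprintf("%s_%s_t%03d", scenario$caseId, scenario$movieId, idn)
  }
  k <- 0L
  for (u in seq_len(nrow(units))) {
    type <- units$track_type[u]
    if (units$size[u] == 2L) {
      pair <- .simCoupledPair(type, par, nF, anchors[u, ], box)
      for (xyz in pair) {
        k <- k + 1L
        dfs[[k]] <- .trackDf(nextId(), xyz, par, units$marker[u],
                             scenario$frameIntervalMin, box,
                             scenario$caseId, scenario$movieId,
                             scenario$diagnosis, type, units$action_type[u])
      }
    } else {
      xyz <- .simPath(type, par, nF, anchors[u, ], box)
      k <- k + 1L
      dfs[[k]] <- .trackDf(nextId(), xyz, par, units$marker[u],
                           scenario$frameIntervalMin, box,
                           scenario$caseId, scenario$movieId,
                           scenario$diagnosis, type, units$action_type[u])
    }
  }
  points <- do.call(rbind, dfs)
  tracks <- TrackSet(points, frameIntervalMin = scenario$frameIntervalMin)
  info <- trackInfo(tracks)
  labels <- data.frame(track_id = info$track_id,
                       track_type = info$tracktype,
                       action_type = info$actiontype,
                       stringsAsFactors = FALSE)
  list(tracks = tracks, labels = labels)
}

#' Simulate a labeled multi-movie scenario
#'
#' Runs \code{\link{simulateMovie}} for several movies with derived seeds
#' and distinct movie ids, pooling the result. The default — six movies at
#' the default mix — is the package's 600-track reference cohort for
#' classifier validation.
#'
#' @param nMovies number of movies (default 6).
#' @param seed integer base seed; movie m uses \code{seed + 101 * m}.
#' @param diagnosis cohort label applied to all movies.
#' @param caseId case id prefix (one case per movie).
#' @param ... further arguments to \code{\link{scenarioConfig}}.
#' @return list(tracks, labels) as in \code{\link{simulateMovie}}.
#' @export
simulateScenarioSet <- function(nMovies = 6L, seed = 1L,
                                diagnosis = "unspecified",
                                caseId = "case", ...) {
  out <- lapply(seq_len(nMovies), function(m) {
    sc <- scenarioConfig(seed = as.integer(seed + 101L * m),
                         diagnosis = diagnosis,
                         caseId = sprintf("%s%02d", caseId, m),
                         movieId = sprintf("movie%02d", m), ...)
    simulateMovie(sc)
  })
  points <- do.call(rbind, lapply(out, function(o) trackPoints(o$tracks)))
  fi <- frameInterval(out[[1L]]$tracks)
  list(tracks = TrackSet(points, frameIntervalMin = fi),
       labels = do.call(rbind, lapply(out, `[[`, "labels")))
}

.cohortCombos <- function(kind, markers = c("CD20", "PD1")) {
  ## per-marker, per-movie archetype mixes: track-type fractions
  ## reactive 45/40/15 and neoplastic 80/17/3 (of 40 tracks)
  base <- if (kind == "reactive") {
    data.frame(track_type  = c("LM", "LM", "MT", "MT", "LD"),
               action_type = c("PC", "IC", "IC", "AC", "AC"),
               n           = c(10L,  8L,   8L,   8L,   6L))
  } else {
    data.frame(track_type  = c("LM", "LM", "MT", "MT", "LD"),
               action_type = c("PC", "IC", "IC", "AC", "AC"),
               n           = c(24L,  8L,   4L,   3L,   1L))
  }
  out <- do.call(rbind, lapply(markers, function(m)
    cbind(data.frame(marker = m, stringsAsFactors = FALSE), base)))
  rownames(out) <- NULL
  out
}

#' Simulate a reactive-versus-neoplastic cohort
#'
#' Generates two labeled groups of movies emulating the qualitative contrast
#' between reactive and neoplastic lymphoid tissue: the neoplastic group has
#' a much higher fraction of low-motion/passive cells (track-type mix 80/17/3
#' percent LM/MT/LD versus 45/40/15 in the reactive group), hence lower mean
#' speed and fewer contacts. Returns one combined TrackSet (group encoded in
#' the \code{diagnosis} column) plus a movie metadata table.
#'
#' @param nMoviesPerGroup movies per group (default 3).
#' @param seed integer base seed.
#' @param ... further arguments to \code{\link{scenarioConfig}} (e.g.
#'   \code{nFrames}, \code{overlap}).
#' @return list(tracks, labels, metadata); metadata has one row per movie
#'   (case_id, movie_id, diagnosis, marker).
#' @export
simulateCohort <- function(nMoviesPerGroup = 3L, seed = 1L, ...) {
  reactive <- simulateScenarioSet(nMovies = nMoviesPerGroup, seed = seed,
                                  diagnosis = "reactive", caseId = "rcase",
                                  combos = .cohortCombos("reactive"), ...)
  neoplastic <- simulateScenarioSet(nMovies = nMoviesPerGroup,
                                    seed = seed + 50021L,
                                    diagnosis = "neoplastic",
                                    caseId = "ncase",
                                    combos = .cohortCombos("neoplastic"), ...)
  points <- rbind(trackPoints(reactive$tracks),
                  trackPoints(neoplastic$tracks))
  tracks <- TrackSet(points, frameIntervalMin =
                       frameInterval(reactive$tracks))
  info <- trackInfo(tracks)
  meta <- unique(info[c("case_id", "movie_id", "diagnosis")])
  meta$marker <- vapply(
    seq_len(nrow(meta)), function(i)
      paste(sort(unique(info$marker[info$case_id == meta$case_id[i] &
                                    info$movie_id == meta$movie_id[i]])),
            collapse = "+"), "")
  rownames(meta) <- NULL
  list(tracks = tracks,
       labels = rbind(reactive$labels, neoplastic$labels),
       metadata = meta)
}

#' Read a scenario configuration from YAML
#'
#' Reads the fields of \code{\link{scenarioConfig}} from a YAML file;
#' \code{combos} is given as a list of records with keys marker,
#' track_type, action_type, n.
#'
#' @param path YAML file path.
#' @return A \code{\link{scenarioConfig}}.
#' @export
readScenario <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$combos))
    y$combos <- do.call(rbind, lapply(y$combos, function(r) {
      ## YAML 1.1 reads a bare `n` key as boolean FALSE; accept both
      cnt <- if (!is.null(r[["n"]])) r[["n"]] else r[["FALSE"]]
      data.frame(marker = r$marker, track_type = r$track_type,
                 action_type = r$action_type, n = as.integer(cnt),
                 stringsAsFactors = FALSE)
    }))
  if (!is.null(y$boxUm)) y$boxUm <- as.numeric(y$boxUm)
  do.call(scenarioConfig, y)
}
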