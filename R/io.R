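#' Read and write trial tables as CSV
#'
#' Trial CSVs are comma-separated UTF-8 with a header row and '.' decimal;
#' response times are seconds. Columns written: \code{participant,
#' condition, coherence, match, discriminability, choice, rt, correct,
#' censored} (missing metadata columns are filled with \code{NA}).
#' Numeric values round-trip losslessly (15 significant digits).
#'
#' @param trials Trial table.
#' @param path File path.
#' @param participant Participant id used when the table has no
#'   \code{participant} column.
#' @return \code{write_trials} returns \code{path} invisibly;
#'   \code{read_trials} returns a data.frame.
#' @export
write_trials <- function(trials, path, participant = 1L) {
  cols <- c("participant", "condition", "coherence", "match",
            "discriminability", "choice", "rt", "correct", "censored")
  if (is.null(trials$participant)) trials$participant <- participant
  for (cl in cols) if (is.null(trials[[cl]])) trials[[cl]] <- NA
  out <- trials[, cols, drop = FALSE]
  for (cl in c("match", "rt")) {
    out[[cl]] <- formatC(out[[cl]], digits = 15, format = "g")
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("correct", "censored")) {
    if (!is.null(df[[cl]])) df[[cl]] <- as.logical(df[[cl]])
  }
  df
}

#' Read and write summary-vector matrices as CSV
#'
#' One simulated participant per row; the header is the layout
#' descriptor, so layouts round-trip exactly.
#'
#' @param summaries Matrix (or single named vector) of summary rows.
#' @param path File path.
#' @export
write_summaries <- function(summaries, path) {
  m <- if (is.matrix(summaries)) summaries else t(as.matrix(summaries))
  df <- as.data.frame(m)
  write.csv(format(df, digits = 15, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  as.matrix(read.csv(path, check.names = FALSE))
}

#' Read and write evidence profiles as CSV
#'
#' Two-column CSV (bin center, mass) preceded by a '#'-prefixed metadata
#' header block recording the breaks, sample size and normalization flag.
#'
#' @param profile An [evidence_profile()].
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "evidence_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) vapply(x, function(v) sprintf("%.15g", v),
                            character(1))
  writeLines(c(
    sprintf("# n: %d", profile$n),
    sprintf("# normalized: %s", profile$normalized),
    sprintf("# breaks: %s", paste(num(profile$breaks), collapse = " "))),
    con)
  writeLines("mid,mass", con)
  writeLines(paste(num(profile$mids), num(profile$mass), sep = ","), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(paste0("^# ", key, ": "), "",
                           grep(paste0("^# ", key, ":"), hdr, value = TRUE))
  brk <- strsplit(get("breaks"), " ")[[1]]
  breaks <- as.numeric(brk[nzchar(brk)])
  body <- read.csv(text = lines[!grepl("^#", lines)])
  structure(list(breaks = breaks, mids = body$mid, mass = body$mass,
                 n = as.integer(get("n")),
                 normalized = as.logical(get("normalized"))),
            class = "evidence_profile")
}

#' Run configuration
#'
#' A serializable key/value tree (YAML) describing priors, design,
#' simulation settings, network settings and seeds; a run is reproducible
#' from its config plus seed alone.
#'
#' @param priors A [prior_spec()].
#' @param design A [design_spec()].
#' @param n_participants Simulated participants in a fixture set.
#' @param model_class Generative class for fixtures.
#' @param dt,t_max,frame_rate Simulation settings (seconds, seconds, Hz).
#' @param seed Integer seed.
#' @param network List of network settings (hidden, decay, maxit).
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(priors = prior_spec(), design = design_spec(),
                       n_participants = 34,
                       model_class = c("gsr", "diffusion", "accumulator"),
                       dt = 0.001, t_max = 10, frame_rate = 60,
                       seed = 1L,
                       network = list(hidden = 40, decay = 1e-3,
                                      maxit = 300)) {
  model_class <- match.arg(model_class)
  structure(list(priors = priors, design = design,
                 n_participants = as.integer(n_participants),
                 model_class = model_class, dt = dt, t_max = t_max,
                 frame_rate = frame_rate, seed = as.integer(seed),
                 network = network),
            class = "run_config")
}

#' @rdname run_config
#' @param config A \code{run_config}.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(
    priors = lapply(unclass(config$priors), as.list),
    design = list(
      coherence_levels = unique(config$design$coherence),
      match_levels = unique(config$design$match),
      discriminability_levels = unique(config$design$discriminability),
      trials_per_condition = attr(config$design, "trials_per_condition")),
    n_participants = config$n_participants,
    model_class = config$model_class,
    dt = config$dt, t_max = config$t_max, frame_rate = config$frame_rate,
    seed = config$seed, network = config$network)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  pr <- do.call(prior_spec, lapply(x$priors, unlist))
  ds <- design_spec(coherence_levels = unlist(x$design$coherence_levels),
                    match_levels = unlist(x$design$match_levels),
                    discriminability_levels =
                      unlist(x$design$discriminability_levels),
                    trials_per_condition = x$design$trials_per_condition)
  run_config(priors = pr, design = ds,
             n_participants = x$n_participants,
             model_class = x$model_class, dt = x$dt, t_max = x$t_max,
             frame_rate = x$frame_rate, seed = x$seed,
             network = x$network)
}

#' Generate a seeded fixture set of simulated participants
#'
#' Produces simulated participants with known generative class and
#' parameters in the shape of the application study (34 participants x
#' 120 trials by default), writes the trial CSV and a ground-truth
#' manifest, and returns everything in memory. Regeneration from the same
#' config and seed is byte-identical.
#'
#' @param config A [run_config()].
#' @param dir Output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param seed Overrides \code{config$seed} if given.
#' @return A list of class \code{"fixture_set"}: \code{trials} (all
#'   participants), \code{truth} (one row per participant with the
#'   generative class and flattened parameters), \code{config}.
#' @export
generate_fixtures <- function(config = run_config(), dir = NULL,
                              seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- if (is.null(seed)) config$seed else seed
  with_seed(seed, {
    np <- config$n_participants
    all_trials <- vector("list", np)
    truth <- vector("list", np)
    for (p in seq_len(np)) {
      repeat {
        base <- sample_application_parameters(config$model_class,
                                              config$design,
                                              prior = config$priors,
                                              with_s_v = TRUE)
        cm <- build_condition_parameters(base, config$design)
        tr <- simulate_dataset(cm, dt = config$dt, t_max = config$t_max)
        # every condition must retain at least one uncensored trial,
        # mirroring the training-corpus resampling rule
        if (all(cm$condition %in% tr$condition[!tr$censored])) break
      }
      tr$participant <- p
      all_trials[[p]] <- tr
      truth[[p]] <- data.frame(participant = p,
                               model_class = config$model_class,
                               t(application_target_vector(base)))
    }
    trials <- if (np > 0) do.call(rbind, all_trials) else
      empty_trial_table(config$design)
    truth_df <- if (np > 0) do.call(rbind, truth) else
      data.frame(participant = integer(0), model_class = character(0))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_trials(trials, file.path(dir, "trials.csv"))
      write.csv(truth_df, file.path(dir, "truth.csv"), row.names = FALSE)
      write_run_config(config, file.path(dir, "config.yaml"))
    }
    structure(list(trials = trials, truth = truth_df, config = config,
                   seed = seed),
              class = "fixture_set")
  })
}

empty_trial_table <- function(design) {
  data.frame(choice = character(0), rt = numeric(0),
             decision_time = numeric(0), n_steps = integer(0),
             censored = logical(0), x = numeric(0), y = numeric(0),
             correct = logical(0), condition = character(0),
             gamma = numeric(0), coherence = numeric(0),
             match = numeric(0), discriminability = numeric(0),
             participant = integer(0), stringsAsFactors = FALSE)
}

#' Serialize priors to/from YAML
#'
#' Keys are exactly \code{phi, mu_mag, theta, tau, nu, gamma}.
#'
#' @param prior A [prior_spec()].
#' @param path YAML file path.
#' @export
write_prior_spec <- function(prior, path) {
  stopifnot(inherits(prior, "prior_spec"))
  yaml::write_yaml(lapply(unclass(prior), as.list), path, precision = 15)
  invisible(path)
}

#' @rdname write_prior_spec
#' @export
read_prior_spec <- function(path) {
  do.call(prior_spec, lapply(yaml::read_yaml(path), unlist))
}

#' Read and write per-trial stimulus traces as long-format CSV
#'
#' Companion file to the trial CSV: one row per stimulus update with
#' columns \code{participant, trial, frame, sample}.
#'
#' @param trials Trial table with a \code{trace} list-column.
#' @param path File path.
#' @param participant Participant id when the table has none.
#' @export
write_traces <- function(trials, path, participant = 1L) {
  if (is.null(trials$trace)) stop("trials carry no `trace` column")
  pid <- if (is.null(trials$participant)) rep(participant, nrow(trials))
         else trials$participant
  n_per <- vapply(trials$trace, length, integer(1))
  out <- data.frame(
    participant = rep(pid, n_per),
    trial = rep(seq_len(nrow(trials)), n_per),
    frame = unlist(lapply(n_per, seq_len)),
    sample = unlist(trials$trace))
  out$sample <- formatC(out$sample, digits = 15, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  split(df$sample, interaction(df$participant, df$trial, drop = TRUE,
                               lex.order = TRUE))
}

#' Persist a training corpus as paired CSV matrices plus a manifest
#'
#' Writes \code{inputs.csv}, \code{targets.csv} and \code{manifest.yaml}
#' (mode, layout, seed, trial count, resample count, content checksum)
#' into a directory, and reads them back.
#'
#' @param ts A [generate_training_set()] result.
#' @param dir Directory path (created if needed).
#' @export
write_training_set <- function(ts, dir) {
  stopifnot(inherits(ts, "training_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_summaries(ts$inputs, file.path(dir, "inputs.csv"))
  tg <- if (is.matrix(ts$targets)) ts$targets else
    cbind(label = ts$targets)
  write_summaries(tg, file.path(dir, "targets.csv"))
  yaml::write_yaml(list(mode = ts$mode, layout = ts$layout,
                        seed = ts$seed, n_trials = ts$n_trials,
                        n_rows = nrow(ts$inputs),
                        n_resampled = ts$n_resampled,
                        checksum = sum(ts$inputs) + sum(tg)),
                   file.path(dir, "manifest.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  inputs <- read_summaries(file.path(dir, "inputs.csv"))
  tg <- read_summaries(file.path(dir, "targets.csv"))
  targets <- if (man$mode == "classify") as.numeric(tg[, "label"]) else tg
  structure(list(inputs = inputs, targets = targets, params = NULL,
                 mode = man$mode, layout = man$layout,
                 design = NULL, n_trials = man$n_trials,
                 n_resampled = man$n_resampled, seed = man$seed),
            class = "training_set")
}
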