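#' Default run configuration
#'
#' Bundles all experiment parameters with the standard settings: 500
#' collocation points per boundary, 50 time instants over a 690 ms
#' heartbeat, Matern/sine-power covariance (`rho = 50` mm,
#' `sigma2 = 4/3`, tolerance `1e-4`), noise variance `1e-8`, the default
#' regularisation parameters, and sparse/Halton quadrature budgets.
#' Every random operation derives its seed from the single `seed` entry.
#'
#' @param ... Overrides of the default entries (partial lists are merged
#'   recursively one level deep).
#' @return A nested named list (class `run_config`).
#' @export
run_config <- function(...) {
  cfg <- list(
    geometry = torso_params(),
    discretisation = list(n_sigma = 500L, n_gamma = 500L, n_t = 50L),
    covariance = list(rho = 50, sigma2 = 4 / 3, tol = 1e-4),
    potential = potential_params(),
    noise = list(variance = 1e-8, seed = 1L),
    regularisation = list(kind = "h12", lambda = NULL, beta = 1e-5),
    quadrature = list(method = "sparse", node_budget = 18000,
                      qmc_n = 1e5, snapshot_t = 100),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("run_config", "list"))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Write / read a space-time potential field as CSV
#'
#' Layout: first column `s` with the curvilinear coordinates, remaining
#' columns one per time instant, named `t<value>`; full double precision.
#' On read, time columns are restored in increasing time order whatever
#' their order in the file.
#'
#' @param field Numeric matrix (`n x n_t`).
#' @param s Curvilinear coordinates (length `n`).
#' @param times Time instants in ms (length `n_t`).
#' @param path File path.
#' @return `write_field` returns `path` invisibly; `read_field` returns a
#'   list with `field`, `s`, `times`.
#' @export
write_field <- function(field, s, times, path) {
  field <- as.matrix(field)
  df <- cbind(s, field)
  colnames(df) <- c("s", sprintf("t%.10g", times))
  df <- apply(df, 2, formatC, digits = 17, format = "g")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, "s,"))
    stopf("malformed field file %s at line 1: expected header 's,t...'",
          path)
  df <- utils::read.csv(path, check.names = FALSE)
  tn <- setdiff(names(df), "s")
  if (!all(grepl("^t", tn)))
    stopf("malformed field file %s at line 1: bad time columns", path)
  times <- as.numeric(sub("^t", "", tn))
  ord <- order(times)
  list(field = unname(as.matrix(df[tn][ord])), s = df$s,
       times = times[ord])
}

stage_names <- c("generate-geometry", "build-kl", "forward", "make-data",
                 "inverse", "uq-forward", "uq-inverse", "convergence")

stage_manifest <- function(dir, stage, config, extra = list()) {
  man <- c(list(stage = stage, config_hash = config_hash(config),
                seed = config$seed,
                package_version = as.character(
                  utils::packageVersion("ecguq"))),
           extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_is_current <- function(dir, config) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) return(FALSE)
  man <- tryCatch(jsonlite::read_json(path), error = function(e) NULL)
  identical(man$config_hash, unname(config_hash(config)))
}

require_stage <- function(out_root, stage) {
  dir <- file.path(out_root, stage)
  if (!dir.exists(dir))
    stopf("missing dependency: run stage '%s' first", stage)
  dir
}

#' Run one experiment stage
#'
#' Orchestrates the reproducible pipeline: each stage writes its outputs
#' and a JSON manifest (configuration hash, seed, package version) into
#' `<out>/<stage>/`; a stage whose manifest matches the current
#' configuration hash is reused, a missing upstream stage is reported by
#' name.  Stage seeds are derived from the global seed by a fixed
#' counter per stage.
#'
#' @param config A [run_config()].
#' @param stage One of `"generate-geometry"`, `"build-kl"`, `"forward"`,
#'   `"make-data"`, `"inverse"`, `"uq-forward"`, `"uq-inverse"`,
#'   `"convergence"`.
#' @param out Output root directory.
#' @param quiet Suppress progress messages.
#' @return The stage directory, invisibly.
#' @export
run_experiment <- function(config, stage, out, quiet = FALSE) {
  if (!stage %in% stage_names)
    stopf("unknown stage '%s' (expected one of: %s)", stage,
          paste(stage_names, collapse = ", "))
  dir <- file.path(out, stage)
  if (stage_is_current(dir, config)) {
    if (!quiet) message(sprintf("stage %s is current, reusing", stage))
    return(invisible(dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  istage <- match(stage, stage_names)
  stage_seed <- derive_seed(config$seed, istage)
  nd <- config$discretisation
  pot <- do.call(potential_params, config$potential)
  load_geometry <- function()
    read_geometry(require_stage(out, "generate-geometry"))
  extra <- list()
  if (stage == "generate-geometry") {
    gp <- config$geometry
    gp$seed <- derive_seed(config$seed, 0L)
    geom <- synthesize_torso(do.call(torso_params, gp))
    write_geometry(geom, dir)
  } else if (stage == "build-kl") {
    geom <- load_geometry()
    model <- covariance_model(rho = config$covariance$rho,
                              sigma2 = config$covariance$sigma2,
                              period = geom$period)
    kl <- build_kl(geom, model, tol = config$covariance$tol,
                   n_sigma = nd$n_sigma)
    say("KL expansion: K = %d modes", kl$rank)
    write_kl(kl, dir)
    extra <- list(rank = kl$rank)
  } else if (stage %in% c("forward", "make-data")) {
    geom <- load_geometry()
    u <- potential_field(nd$n_sigma, geom$times, pot)
    cache <- chest_blocks_cache(geom$chest, nd$n_gamma)
    y <- vapply(seq_along(geom$times), function(j) {
      blocks <- assemble_blocks(geom$pericardium[[j]], geom$chest,
                                nd$n_sigma, chest_cache = cache)
      forward_solve(blocks, u[, j])
    }, numeric(nd$n_gamma))
    if (stage == "forward") {
      write_field(u, collocation_grid(nd$n_sigma), geom$times,
                  file.path(dir, "pericardial.csv"))
      write_field(y, collocation_grid(nd$n_gamma), geom$times,
                  file.path(dir, "chest.csv"))
    } else {
      rec <- add_noise(y, config$noise$variance,
                       derive_seed(config$seed, istage))
      say("chest data SNR: %.1f dB", rec$snr_db)
      write_field(rec$y, collocation_grid(nd$n_gamma), geom$times,
                  file.path(dir, "data.csv"))
      extra <- list(snr_db = rec$snr_db)
    }
  } else if (stage == "inverse") {
    geom <- load_geometry()
    yd <- read_field(file.path(require_stage(out, "make-data"), "data.csv"))
    cache <- chest_blocks_cache(geom$chest, nd$n_gamma)
    rc <- config$regularisation
    urec <- vapply(seq_along(geom$times), function(j) {
      blocks <- assemble_blocks(geom$pericardium[[j]], geom$chest,
                                nd$n_sigma, chest_cache = cache)
      ops <- build_transfer(blocks)
      lambda <- rc$lambda
      if (identical(lambda, "auto"))
        lambda <- l_curve_select(ops, yd$field[, j], rc$kind,
                                 beta = rc$beta)$lambda
      inverse_solve(ops, yd$field[, j],
                    regularisation_spec(rc$kind, lambda, rc$beta))
    }, numeric(nd$n_sigma))
    write_field(urec, collocation_grid(nd$n_sigma), yd$times,
                file.path(dir, "pericardial_reconstruction.csv"))
  } else if (stage %in% c("uq-forward", "uq-inverse", "convergence")) {
    geom <- load_geometry()
    qc <- config$quadrature
    snap <- uq_snapshot(geom, t = qc$snapshot_t, n_sigma = nd$n_sigma,
                        tol = config$covariance$tol,
                        params = pot)
    say("snapshot KL rank K = %d", snap$kl$rank)
    if (stage == "uq-forward") {
      evf <- forward_evaluator(snap)
      rule <- if (qc$method == "halton") halton_rule(snap$kl$rank, qc$qmc_n)
        else {
          alpha <- anisotropy_weights(snap$kl)
          lv <- pick_sparse_levels(snap$kl$rank, alpha, qc$node_budget)
          sparse_rule(snap$kl$rank, lv[length(lv)], alpha)
        }
      mom <- estimate_moments(rule, evf)
      for (nm in c("m1", "m2", "std"))
        write_field(mom[[nm]], collocation_grid(nd$n_gamma), qc$snapshot_t,
                    file.path(dir, paste0(nm, ".csv")))
      extra <- list(n_nodes = mom$n_nodes)
    } else if (stage == "uq-inverse") {
      res <- inverse_uq_study(snap, node_budget = qc$node_budget,
                              qmc_n = qc$qmc_n,
                              noise_variance = config$noise$variance,
                              seed = stage_seed)
      jsonlite::write_json(list(rates = as.list(res$rates),
                                final_rates = as.list(res$final_rates),
                                max_std = as.list(res$max_std),
                                k = res$k),
                           file.path(dir, "rates.json"),
                           auto_unbox = TRUE, digits = NA)
      extra <- list(k = res$k)
    } else {
      res <- forward_uq_study(snap, node_budget = qc$node_budget,
                              qmc_n = qc$qmc_n)
      jsonlite::write_json(
        list(table = res$study$table, rate = res$rate,
             discrepancy_m1 = res$discrepancy_m1,
             discrepancy_m2 = res$discrepancy_m2, k = res$k),
        file.path(dir, "convergence.json"), auto_unbox = TRUE,
        digits = NA, dataframe = "columns")
      extra <- list(rate = res$rate, k = res$k)
    }
  }
  stage_manifest(dir, stage, config, extra)
  invisible(dir)
}
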