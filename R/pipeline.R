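## End-to-end experiment orchestration: generate (or load) surfaces,
## filter, compute texture parameters and microwear counts, run the
## robust group statistics on every variable, and the discriminant
## analysis on the headline variables.

#' Default experiment configuration
#'
#' A single nested list carrying every protocol constant with its
#' default: the 80% measured-point threshold, filter cutoffs and
#' F-operator degree, texture conditions (s = 0.2, p = 10%, q = 80%,
#' c = 1 µm, p = 50%/q = 97.5%, 5% Wolf pruning), the 300 µm counting
#' square and aspect threshold 4, 15% trimming and alpha = 0.05, and
#' the discriminant stepping thresholds F-enter = 1 / F-remove = 0.9
#' with 90% centroid confidence.
#'
#' @param grid_n Grid points per side for synthetic surfaces; default
#'   512 (160 µm field).
#' @return A nested configuration list.
#' @export
default_experiment_config <- function(grid_n = 512) {
  list(
    groups = list(silica_GO = 3.2, silica_LO = 3.0),
    surface = list(grid_n = grid_n, extent_um = 160, noise_sd = NULL,
                   dropout_rate = 0.05),
    io = list(measured_threshold = 0.80),
    filtering = list(s_cutoff_um = 2.5, l_cutoff_um = 25, f_degree = 2),
    texture = list(s = 0.2, p_pct = 10, q_pct = 80, smr_c_um = 1,
                   sxp_p_pct = 50, sxp_q_pct = 97.5,
                   pruning_fraction = 0.05,
                   families = c("height", "spatial", "hybrid",
                                "functional", "segmentation")),
    microwear = list(square_um = 300, aspect_threshold = 4),
    stats = list(trim = 0.15, alpha = 0.05, smm_nsim = 20000),
    da = list(f_enter = 1, f_remove = 0.9, confidence = 0.90,
              variables = c("Np", "Ls_um", "Sda_primary", "Sp_S-L"))
  )
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' Values present in the file override the defaults of
#' [default_experiment_config()]; everything else keeps its default.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A full configuration list.
#' @export
read_experiment_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_experiment_config(), user)
}

config_conditions <- function(config) {
  tx <- config$texture
  list(smr_c_um = tx$smr_c_um, p_pct = tx$p_pct, q_pct = tx$q_pct,
       sxp_p_pct = tx$sxp_p_pct, sxp_q_pct = tx$sxp_q_pct, s = tx$s)
}

#' Run the full wear-analysis experiment
#'
#' Generates the synthetic experiment bundle (or analyses supplied
#' surfaces), runs the S-filter / F-operator / L-filter chain, computes
#' the texture parameter set on the primary, S-F and S-L stages and the
#' microwear counts, applies the robust group statistics to the silica
#' covariate, every microwear variable and every texture parameter on
#' every stage, and runs the forward-stepping canonical discriminant
#' analysis on the headline variables (Np, Ls, Sda on the primary
#' surface, Sp on the S-L surface by default). Rerunning with the same
#' configuration and seed reproduces all outputs bit-exactly.
#'
#' @param config Configuration list; see
#'   [default_experiment_config()] / [read_experiment_config()].
#' @param master_seed Integer master seed.
#' @param outdir Optional output directory; when given, all result
#'   tables are written as CSV files stamped with the configuration
#'   hash and seed.
#' @param bundle Optional pre-generated [generate_group_sample()]
#'   bundle (e.g. from loaded real surfaces); when `NULL` one is
#'   generated from `config` and `master_seed`.
#' @return An object of class `experiment_report`: list with
#'   `measurements` (long data frame of all per-animal variables),
#'   `omnibus` (per-variable Welch-Yuen table), `pairwise` (all
#'   pairwise + Cliff rows with dual-significance flags), `profiles`
#'   (per-variable group variability), `da` (discriminant result,
#'   ellipse table and overlap matrix, or `NULL` if skipped), `config`,
#'   `config_hash`, `master_seed`.
#' @export
run_experiment <- function(config = default_experiment_config(),
                           master_seed = 1, outdir = NULL, bundle = NULL) {
  configs <- do.call(default_diet_configs, config$groups)
  if (is.null(bundle)) {
    sf <- config$surface
    bundle <- generate_group_sample(configs, master_seed,
                                    grid_n = sf$grid_n,
                                    extent_um = sf$extent_um,
                                    noise_sd = sf$noise_sd,
                                    dropout_rate = sf$dropout_rate)
  }
  conditions <- config_conditions(config)
  fl <- config$filtering
  mw <- config$microwear
  rows <- list()
  for (a in bundle$animals) {
    rec <- data.frame(animal_id = a$animal_id, group = a$group,
                      variable = "SC", stage = NA, value = a$silica_mg_g)
    rows[[length(rows) + 1]] <- rec
    counts <- count_microwear(a$counting_features, mw$square_um,
                              aspect_threshold = mw$aspect_threshold)
    mwt <- tidy_microwear(counts, a$animal_id, a$group)
    rows[[length(rows) + 1]] <- data.frame(animal_id = mwt$animal_id,
                                           group = mwt$group,
                                           variable = mwt$variable,
                                           stage = NA, value = mwt$value)
    if (!is.null(a$height_map)) {
      v <- validate_measured_fraction(a$height_map,
                                      config$io$measured_threshold)
      if (v$status == "reject") {
        warning(sprintf("surface %s rejected (measured fraction %.3f); skipped",
                        a$animal_id, v$fraction))
        next
      }
      filled <- fill_nonmeasured(a$height_map)
      stages <- filter_chain(filled, fl$s_cutoff_um, fl$l_cutoff_um,
                             fl$f_degree)
      for (hm in stages) {
        tp <- compute_all(hm, conditions,
                          pruning_fraction = config$texture$pruning_fraction,
                          families = config$texture$families)
        td <- tidy_texture_params(tp, a$animal_id, a$group)
        rows[[length(rows) + 1]] <- data.frame(animal_id = td$animal_id,
                                               group = td$group,
                                               variable = td$parameter,
                                               stage = td$stage,
                                               value = td$value)
      }
    }
  }
  meas <- do.call(rbind, rows)
  meas$key <- ifelse(is.na(meas$stage), meas$variable,
                     paste(meas$variable, meas$stage, sep = "_"))
  st <- config$stats
  omni_rows <- list(); pw_rows <- list(); prof_rows <- list()
  for (key in unique(meas$key)) {
    sub <- meas[meas$key == key & is.finite(meas$value), ]
    if (length(unique(sub$group)) < 2 || any(table(sub$group) < 4)) next
    res <- tryCatch(
      group_compare(sub$value, sub$group, variable = key, trim = st$trim,
                    alpha = st$alpha, nsim = st$smm_nsim),
      error = function(e) NULL)
    if (is.null(res)) next
    o <- res$omnibus
    omni_rows[[key]] <- data.frame(
      block = variable_block(key), variable = key, Ft = o$Ft, p = o$p,
      nu1 = o$nu1, nu2 = o$nu2)
    pw <- res$pairwise
    pw$variable <- key
    pw_rows[[key]] <- pw
    pr <- res$profile
    pr$variable <- key
    prof_rows[[key]] <- pr
  }
  da <- run_da(meas, config)
  report <- structure(list(
    measurements = meas,
    omnibus = do.call(rbind, c(omni_rows, list(make.row.names = FALSE))),
    pairwise = do.call(rbind, c(pw_rows, list(make.row.names = FALSE))),
    profiles = do.call(rbind, c(prof_rows, list(make.row.names = FALSE))),
    da = da, config = config, config_hash = config_hash(config),
    master_seed = master_seed
  ), class = "experiment_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

variable_block <- function(key) {
  if (key == "SC") return("silica")
  if (key %in% c("Np", "Np5", "Np10", "Ns", "Nws5", "Nws10", "Ls_um"))
    return("microwear (A)")
  if (endsWith(key, "_primary")) return("texture (A)")
  if (endsWith(key, "_S-F")) return("texture (B)")
  if (endsWith(key, "_S-L")) return("texture (C)")
  "other"
}

## discriminant analysis on the configured headline variables
run_da <- function(meas, config) {
  vars <- config$da$variables
  wide <- stats::reshape(meas[meas$key %in% vars,
                              c("animal_id", "group", "key", "value")],
                         idvar = c("animal_id", "group"),
                         timevar = "key", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  have <- intersect(vars, names(wide))
  wide <- wide[stats::complete.cases(wide[, have, drop = FALSE]), ]
  if (length(have) < 2 || any(table(wide$group) < 3)) {
    warning("discriminant analysis skipped: too few variables or animals")
    return(NULL)
  }
  X <- as.matrix(wide[, have, drop = FALSE])
  selected <- stepwise_select(X, wide$group, config$da$f_enter,
                              config$da$f_remove)
  if (length(selected) < 2) {
    # a 2-D factor space needs at least two variables: fall back to the
    # two strongest candidates by single-variable partial F
    k <- length(unique(wide$group)); n <- nrow(X)
    f1 <- vapply(colnames(X), function(v) {
      lam <- wilks_lambda(X, wide$group, v)
      (n - k) / (k - 1) * (1 - lam) / lam
    }, numeric(1))
    selected <- names(sort(f1, decreasing = TRUE))[1:2]
  }
  cda <- canonical_da(X[, selected, drop = FALSE], wide$group)
  if (ncol(cda$scores) < 2) return(list(selected = selected, cda = cda,
                                        ellipses = NULL, overlap = NULL))
  ell <- centroid_ellipses(cda$scores, wide$group, config$da$confidence)
  # the overlap *pattern* is judged on the groups' factor spaces (data
  # concentration regions), whose size reflects within-group variability
  fsp <- factor_space_ellipses(cda$scores, wide$group, config$da$confidence)
  gl <- fsp$group
  overlap <- matrix(NA, length(gl), length(gl), dimnames = list(gl, gl))
  for (i in seq_along(gl)) for (j in seq_along(gl))
    overlap[i, j] <- if (i == j) TRUE else
      ellipses_overlap(fsp[i, ], fsp[j, ])
  list(selected = selected, cda = cda, ellipses = ell,
       factor_spaces = fsp, overlap = overlap,
       scores = data.frame(animal_id = wide$animal_id, group = wide$group,
                           score1 = cda$scores[, 1],
                           score2 = cda$scores[, 2]))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> seed %s, config %s\n", x$master_seed,
              x$config_hash))
  cat(sprintf("  %d variables tested; %d dual-significant pairwise contrasts\n",
              length(unique(x$omnibus$variable)),
              sum(x$pairwise$dual_significant, na.rm = TRUE)))
  if (!is.null(x$da))
    cat("  DA variables:", paste(x$da$selected, collapse = ", "), "\n")
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash=%s master_seed=%s", report$config_hash,
                   report$master_seed)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wr(report$measurements, "measurements.csv")
  wr(report$omnibus, "omnibus.csv")
  wr(report$pairwise, "pairwise.csv")
  wr(report$profiles, "profiles.csv")
  if (!is.null(report$da)) {
    wr(report$da$scores, "da_scores.csv")
    wr(report$da$ellipses, "da_ellipses.csv")
    if (!is.null(report$da$factor_spaces))
      wr(report$da$factor_spaces, "da_factor_spaces.csv")
    co <- report$da$cda$coefficients
    wr(data.frame(variable = rownames(co), co, row.names = NULL),
       "da_coefficients.csv")
  }
  writeLines(c(stamp, yaml::as.yaml(report$config)),
             file.path(outdir, "config_resolved.yaml"))
  invisible(outdir)
}

#' Summarize an experiment report as markdown
#'
#' One human-readable summary: the dual-significant parameters per
#' block/stage, the per-group interquartile-range ordering of the
#' headline variables, and the discriminant-space overlap structure.
#' Regenerating the summary from the same report gives identical text.
#'
#' @param report An [run_experiment()] result.
#' @return Character vector of markdown lines.
#' @export
summarize_tables <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  lines <- c(sprintf("# Experiment summary (seed %s, config %s)",
                     report$master_seed, report$config_hash), "")
  pw <- report$pairwise
  sig <- pw[!is.na(pw$dual_significant) & pw$dual_significant, ]
  lines <- c(lines, "## Dual-significant contrasts (both robust tests p <= alpha)", "")
  if (nrow(sig) == 0) {
    lines <- c(lines, "no significant contrasts", "")
  } else {
    for (v in unique(sig$variable)) {
      sv <- sig[sig$variable == v, ]
      lines <- c(lines, sprintf("- %s [%s]: %s", v, variable_block(v),
                                paste(sv$group1, sv$group2, sep = "-",
                                      collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "## Group variability (IQR) of headline variables", "")
  for (v in intersect(c("Np", "Ls_um", "Sda_primary", "Sp_S-L"),
                      unique(report$profiles$variable))) {
    pr <- report$profiles[report$profiles$variable == v, ]
    ord <- pr$group[order(-pr$iqr)]
    lines <- c(lines, sprintf("- %s: IQR ordering %s", v,
                              paste(ord, collapse = " > ")))
  }
  if (!is.null(report$da) && !is.null(report$da$overlap)) {
    ov <- report$da$overlap
    lines <- c(lines, "", "## Discriminant factor space", "",
               sprintf("- selected variables: %s",
                       paste(report$da$selected, collapse = ", ")))
    gl <- rownames(ov)
    for (i in seq_along(gl)) for (j in seq_along(gl)) if (i < j)
      lines <- c(lines, sprintf("- %s vs %s 90%% factor spaces: %s",
                                gl[i], gl[j],
                                if (ov[i, j]) "overlap" else "disjoint"))
  }
  lines
}
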