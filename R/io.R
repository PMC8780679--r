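# File formats: two-column xvg-dialect traces, TSV manifests, headered
# TSV profiles and key-value configs/results. All writers emit '#' headers
# sufficient to re-run the producing stage; all readers reject malformed
# input rather than coercing it.

#' Read an umbrella-window trace file
#'
#' Two whitespace-delimited numeric columns (time in ps, z in nm); lines
#' starting with `#` or `@` are skipped (GROMACS xvg pull files parse
#' unchanged). Times must be strictly increasing.
#'
#' @param path file path.
#' @param center,force_constant,temperature,seed bias metadata (usually
#'   supplied from a manifest; the file itself carries only the series).
#' @return a `window_trace`.
#' @export
read_trace <- function(path, center = NA_real_, force_constant = NA_real_,
                       temperature = NA_real_, seed = NA_integer_) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#@]|$)", lines)
  if (!any(keep)) stop(sprintf("no data lines in %s", path))
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop(sprintf("line %d of %s has fewer than two columns",
                 idx[which(nf < 2L)[1]], path))
  times <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  z <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  bad <- which(!is.finite(times) | !is.finite(z))
  if (length(bad))
    stop(sprintf("malformed numeric value at line %d of %s", idx[bad[1]], path))
  if (any(diff(times) <= 0)) {
    k <- which(diff(times) <= 0)[1] + 1L
    stop(sprintf("non-monotone time column at line %d of %s", idx[k], path))
  }
  window_trace(times, z, center, force_constant, temperature, seed)
}

#' Write an umbrella-window trace file
#'
#' @param trace a `window_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  hdr <- c("# umbrella window trace",
           sprintf("# center_nm %.17g", trace$center),
           sprintf("# force_constant_kj_mol_nm2 %.17g", trace$force_constant),
           sprintf("# temperature_K %.17g", trace$temperature),
           sprintf("# seed %s", ifelse(is.na(trace$seed), "NA", trace$seed)),
           "# time_ps z_nm")
  writeLines(c(hdr, sprintf("%.17g %.17g", trace$times, trace$z)), path)
  invisible(path)
}

#' Read a window manifest
#'
#' TSV with required columns window_id, center_nm,
#' force_constant_kj_mol_nm2, seed, trace_path, side; extra columns are
#' preserved. Trace paths are resolved relative to the manifest location
#' and must exist.
#'
#' @param path manifest path.
#' @param check_paths verify that every trace_path resolves (default TRUE).
#' @return a `window_manifest` data.frame with absolute trace paths.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("window_id", "center_nm", "force_constant_kj_mol_nm2",
           "seed", "trace_path", "side")
  missing <- setdiff(req, names(m))
  if (length(missing))
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(m$window_id))
    stop("duplicate window_id in manifest")
  if (!all(m$side %in% c("outer", "inner")))
    stop("manifest side tags must be 'outer' or 'inner'")
  root <- dirname(normalizePath(path))
  m$trace_path <- ifelse(is.na(m$trace_path) | m$trace_path == "NA",
                         NA_character_,
                         ifelse(grepl("^/", m$trace_path), m$trace_path,
                                file.path(root, m$trace_path)))
  if (check_paths) {
    gone <- !is.na(m$trace_path) & !file.exists(m$trace_path)
    if (any(gone))
      stop(sprintf("unresolvable trace path(s): %s",
                   paste(m$trace_path[gone], collapse = ", ")))
  }
  class(m) <- c("window_manifest", "data.frame")
  m
}

#' Write a window manifest
#'
#' @param manifest a `window_manifest` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load all traces referenced by a manifest
#'
#' @param manifest a `window_manifest` (from [read_manifest()]).
#' @param temperature temperature metadata attached to each trace, K.
#' @return list of `window_trace`, in manifest order.
#' @export
load_traces <- function(manifest, temperature = 310) {
  lapply(seq_len(nrow(manifest)), function(i) {
    read_trace(manifest$trace_path[i],
               center = manifest$center_nm[i],
               force_constant = manifest$force_constant_kj_mol_nm2[i],
               temperature = temperature,
               seed = manifest$seed[i])
  })
}

#' Write simulated traces and their manifest to a directory
#'
#' @param sim a [simulate_protocol()] result.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_windows <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- sim$manifest
  for (i in seq_len(nrow(man))) {
    fn <- sprintf("window_%03d.xvg", man$window_id[i])
    write_trace(sim$traces[[i]], file.path(dir, fn))
    man$trace_path[i] <- fn
  }
  write_manifest(man, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Write a PMF profile
#'
#' Three columns (z_nm, dG_kJ_mol, stderr_kJ_mol) with a '#' header
#' recording the reference convention, smoothing, bin width and
#' temperature.
#'
#' @param pmf a `pmf_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  se <- if (is.null(pmf$stderr)) rep(NA_real_, length(pmf$z)) else pmf$stderr
  hdr <- c("# PMF profile",
           sprintf("# reference %s", pmf$reference),
           sprintf("# side %s", pmf$side),
           sprintf("# smoothed %s", pmf$smoothed),
           sprintf("# smoothing_span_nm %s", pmf$smoothing_span %||% 0),
           sprintf("# bin_width_nm %s", pmf$bin_width),
           sprintf("# temperature_K %s", pmf$temperature),
           "# z_nm dG_kJ_mol stderr_kJ_mol")
  writeLines(c(hdr, sprintf("%.17g %.17g %.17g", pmf$z, pmf$dG, se)), path)
  invisible(path)
}

num_meta <- function(x, default = NA_real_) {
  if (is.null(x) || identical(x, "NA")) default else as.numeric(x)
}

read_header_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s+(\\S+)\\s+(\\S+)\\s*$", hdr))
  kv <- Filter(function(x) length(x) == 3L, kv)
  stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, "", 2L))
}

#' Read a PMF profile written by [write_pmf()]
#'
#' @param path file path.
#' @return a `pmf_profile`.
#' @export
read_pmf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- read_header_meta(lines)
  dat <- utils::read.table(text = lines[!grepl("^\\s*([#@]|$)", lines)])
  if (ncol(dat) < 2L) stop(sprintf("%s: expected at least two columns", path))
  se <- if (ncol(dat) >= 3L) {
    v <- as.numeric(dat[[3]]); if (all(is.na(v))) NULL else v
  } else NULL
  pmf_profile(dat[[1]], dat[[2]], stderr = se,
              reference = meta$reference %||% "raw",
              side = meta$side %||% "full",
              smoothed = isTRUE(as.logical(meta$smoothed %||% "FALSE")),
              temperature = num_meta(meta$temperature_K, 310),
              bin_width = num_meta(meta$bin_width_nm))
}

#' Write a diffusivity profile
#'
#' Columns z_nm, D_nm2_per_ps; per-window estimates (mean position,
#' variance, ACF integral, D) go into '#' comments.
#'
#' @param dp a `diffusivity_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diffusivity <- function(dp, path) {
  w <- dp$windows
  hdr <- c("# diffusivity profile (variance/autocorrelation estimator)",
           sprintf("# side %s", dp$side),
           sprintf("# max_lag_ps %s", dp$max_lag),
           sprintf("# acf_rule %s", dp$rule),
           "## window z_mean_nm var_nm2 acf_integral_nm2ps D_nm2_per_ps",
           sprintf("## %d %.8g %.8g %.8g %.8g", w$window, w$z_mean,
                   w$var, w$acf_integral, w$D),
           "# z_nm D_nm2_per_ps")
  writeLines(c(hdr, sprintf("%.17g %.17g", dp$z, dp$D)), path)
  invisible(path)
}

#' Read a diffusivity profile written by [write_diffusivity()]
#'
#' @param path file path.
#' @return a `diffusivity_profile` (window table omitted).
#' @export
read_diffusivity <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- read_header_meta(lines)
  dat <- utils::read.table(text = lines[!grepl("^\\s*([#@]|$)", lines)])
  structure(list(z = dat[[1]], D = dat[[2]],
                 windows = data.frame(),
                 side = meta$side %||% "full",
                 max_lag = num_meta(meta$max_lag_ps),
                 rule = meta$acf_rule %||% "first_zero"),
            class = "diffusivity_profile")
}

#' Write a permeability result as key-value text
#'
#' @param result a `permeability_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  writeLines(c("# permeability result (inhomogeneous solubility-diffusion model)",
               sprintf("R_eff_ps_per_nm = %.17g", result$R_eff),
               sprintf("P_cm_per_s = %.17g", result$P_cm_per_s),
               sprintf("logP = %.17g", result$logP),
               sprintf("z1_nm = %.17g", result$z1),
               sprintf("z2_nm = %.17g", result$z2),
               sprintf("temperature_K = %.17g", result$temperature)), path)
  invisible(path)
}

#' Serialise a run configuration to a key-value file
#'
#' @param config a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = " ")
    else paste(as.character(v), collapse = " ")
  }
  writeLines(c("# memperm run configuration",
               vapply(names(config), function(nm)
                 sprintf("%s = %s", nm, fmt(config[[nm]])), "")), path)
  invisible(path)
}

#' Read a run configuration written by [write_config()]
#'
#' @param path file path.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*([#]|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stop(sprintf("malformed config line: '%s'", lines[bad[1]]))
  vals <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
  num <- function(x) as.numeric(strsplit(x, "\\s+")[[1]])
  run_config(
    temperature = num(vals$temperature),
    bin_width = num(vals$bin_width),
    wham_tol = num(vals$wham_tol),
    wham_max_iter = num(vals$wham_max_iter),
    smoothing_span = num(vals$smoothing_span),
    bulk_edge = num(vals$bulk_edge),
    z1 = num(vals$z1), z2 = num(vals$z2),
    max_lag = num(vals$max_lag),
    acf_rule = vals$acf_rule,
    membrane_mode = vals$membrane_mode,
    support = num(vals$support),
    use_smoothed_pmf = as.logical(vals$use_smoothed_pmf))
}

#' Write a toy bilayer snapshot as plain text
#'
#' Records `box`, one `lipid` line per molecule (leaflet, species,
#' position, mass, triad xy), `orient` lines (lipid id, carbon index,
#' unit vector) and `water` lines.
#'
#' @param snapshot a `toy_bilayer`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  lp <- snapshot$lipids
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# toy bilayer snapshot",
               sprintf("box %.17g %.17g %.17g", snapshot$box[1],
                       snapshot$box[2], snapshot$box[3])), con)
  writeLines(sprintf("lipid %d %s %s %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                     lp$id, lp$leaflet, lp$species, lp$x, lp$y, lp$z, lp$mass,
                     lp$t1x, lp$t1y, lp$t2x, lp$t2y, lp$t3x, lp$t3y), con)
  for (i in seq_len(nrow(lp))) {
    m <- snapshot$orient[[i]]
    writeLines(sprintf("orient %d %d %.17g %.17g %.17g",
                       lp$id[i], seq_len(nrow(m)), m[, 1], m[, 2], m[, 3]), con)
  }
  if (nrow(snapshot$water))
    writeLines(sprintf("water %.17g %.17g %.17g %.17g", snapshot$water$x,
                       snapshot$water$y, snapshot$water$z,
                       snapshot$water$mass), con)
  invisible(path)
}

#' Read a toy bilayer snapshot written by [write_snapshot()]
#'
#' @param path file path.
#' @return a `toy_bilayer`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*([#]|$)", lines)]
  tok <- strsplit(trimws(lines), "\\s+")
  kind <- vapply(tok, `[[`, "", 1L)
  box <- as.numeric(tok[[which(kind == "box")[1]]][-1])
  lt <- tok[kind == "lipid"]
  lipids <- data.frame(
    id = as.integer(vapply(lt, `[[`, "", 2L)),
    leaflet = vapply(lt, `[[`, "", 3L),
    species = vapply(lt, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  numcols <- c("x", "y", "z", "mass", "t1x", "t1y", "t2x", "t2y", "t3x", "t3y")
  for (j in seq_along(numcols))
    lipids[[numcols[j]]] <- as.numeric(vapply(lt, `[[`, "", 4L + j))
  ot <- tok[kind == "orient"]
  oid <- as.integer(vapply(ot, `[[`, "", 2L))
  omat <- do.call(rbind, lapply(ot, function(x) as.numeric(x[4:6])))
  orient <- lapply(lipids$id, function(id)
    omat[oid == id, , drop = FALSE])
  wt <- tok[kind == "water"]
  water <- if (length(wt)) {
    data.frame(x = as.numeric(vapply(wt, `[[`, "", 2L)),
               y = as.numeric(vapply(wt, `[[`, "", 3L)),
               z = as.numeric(vapply(wt, `[[`, "", 4L)),
               mass = as.numeric(vapply(wt, `[[`, "", 5L)))
  } else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    mass = numeric(0))
  structure(list(box = box, lipids = lipids, orient = orient, water = water,
                 n_carbons = if (length(orient)) nrow(orient[[1]]) else 0L,
                 seed = NA_integer_),
            class = "toy_bilayer")
}
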