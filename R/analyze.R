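#' Analyze one pQCT cross-section end to end
#'
#' Runs the full pipeline on one image: [segment_cortex()],
#' [summarize_shape()], and the circular ring model of
#' [circular_estimates()] on the same areas, so shape-sensitive and
#' ring-model outputs sit side by side in one row (the circular model
#' underestimates the circumferences of non-circular sections).
#'
#' @param image A [scan_image()] or a path to a `.raw` / `.tif` / `.png`
#'   file.
#' @param config An [analysis_config()].
#' @param seed `(row, col)` seed on bone, or `NULL` for [auto_seed()].
#' @return A one-row tibble: every [summarize_shape()] column plus
#'   `csa_filled_mm2`, `peri_circ_ring_mm`, `endo_circ_ring_mm`,
#'   `mean_thickness_ring_mm` and `seed_row` / `seed_col`.
#' @examples
#' ph <- rasterize_phantom(phantom_spec(), image_geometry(128, 128, 0.5))
#' analyze_scan(ph$image, analysis_config(width = 128, height = 128))
#' @export
analyze_scan <- function(image, config = analysis_config(), seed = NULL) {
  if (is.character(image)) {
    image <- if (tolower(tools::file_ext(image)) == "raw") {
      read_raw(image, image_geometry(config$width, config$height,
                                     config$voxel_size, config$byte_order))
    } else {
      read_scan(image, config$voxel_size)
    }
  }
  seg <- segment_cortex(image, config, seed)
  res <- summarize_shape(seg)
  csa <- total_csa(image, config$threshold, seg$seed)
  ring <- circular_estimates(csa$csa_filled_mm2, res$cort_csa_mm2)
  out <- dplyr::bind_cols(
    res,
    tibble::tibble(csa_filled_mm2 = csa$csa_filled_mm2,
                   seed_row = seg$seed[1L], seed_col = seg$seed[2L]),
    ring
  )
  class(out) <- class(res)
  attr(out, "segmentation") <- attr(res, "segmentation")
  attr(out, "fits") <- attr(res, "fits")
  out
}

#' Analyze a manifest of scans
#'
#' Iterates `analyze_scan()` over a manifest (CSV with column `path`,
#' optional `seed_row` / `seed_col`). Failures do not stop the batch:
#' each failed scan is reported in the returned `errors` attribute and on
#' the console.
#'
#' @param manifest Path to a manifest CSV or a data frame.
#' @param config An [analysis_config()].
#' @return A tibble of successful rows (one per scan, with `path`);
#'   attribute `"errors"` is a tibble of failed paths and messages.
#' @export
analyze_batch <- function(manifest, config = analysis_config()) {
  man <- if (is.character(manifest)) read.csv(manifest) else manifest
  if (!"path" %in% names(man)) stop("manifest needs a 'path' column")
  rows <- list(); errs <- list()
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    seed <- if (all(c("seed_row", "seed_col") %in% names(man)) &&
                !is.na(man$seed_row[i])) {
      c(man$seed_row[i], man$seed_col[i])
    } else NULL
    res <- tryCatch(analyze_scan(p, config, seed), error = function(e) e)
    if (inherits(res, "error")) {
      message("FAILED ", p, ": ", conditionMessage(res))
      errs[[length(errs) + 1L]] <- tibble::tibble(
        path = p, error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(path = p), tibble::as_tibble(res))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "errors") <- dplyr::bind_rows(errs)
  out
}

cli_usage <- function() {
  paste(
    "usage: pqctshape <command> [options]",
    "",
    "commands:",
    "  analyze <image> [--threshold T] [--voxel V] [--width W] [--height H]",
    "          [--seed R C | --auto-seed] [--open-iterations N]",
    "          [--out results.csv] [--overlay overlay.png]",
    "  batch <manifest.csv> [--threshold T] [--voxel V] [--out results.csv]",
    "  phantom [--shape S] [--out-raw f.raw] [--out-truth f.json]",
    "          [--out-preview f.png] [--width W] [--height H] [--voxel V]",
    "          [--random-seed N]",
    "  compare <table.csv> --outcomes a,b,c [--no-adjust] [--out report.csv]",
    "  render <image> [--threshold T] [--voxel V] [--out overlay.png]",
    sep = "\n")
}

cli_opt <- function(args, flag, default = NULL, n = 1L) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1L] + n > length(args)) stop("missing value for ", flag)
  args[i[1L] + seq_len(n)]
}

cli_config <- function(args) {
  analysis_config(
    threshold = as.numeric(cli_opt(args, "--threshold", 450)),
    voxel_size = as.numeric(cli_opt(args, "--voxel", 0.5)),
    width = as.integer(cli_opt(args, "--width", 283)),
    height = as.integer(cli_opt(args, "--height", 283)),
    open_iterations = as.integer(cli_opt(args, "--open-iterations", 1))
  )
}

#' Command-line entry point
#'
#' Thin driver behind the `inst/cli/pqctshape` script. Parses a
#' subcommand (`analyze`, `batch`, `phantom`, `compare`, `render`),
#' runs the corresponding package functions and returns a shell exit
#' code: 0 on success, 1 on analysis failure (with a stage-named
#' message), 2 on bad arguments.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat(cli_usage(), "\n")
    return(invisible(if (length(args)) 0L else 2L))
  }
  cmd <- args[1L]; rest <- args[-1L]
  code <- tryCatch(
    switch(cmd,
      analyze = cli_analyze(rest),
      batch = cli_batch(rest),
      phantom = cli_phantom(rest),
      compare = cli_compare(rest),
      render = cli_render(rest),
      {
        message("unknown command: ", cmd)
        cat(cli_usage(), "\n")
        2L
      }),
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    })
  invisible(code)
}

cli_analyze <- function(args) {
  target <- args[!startsWith(args, "--")]
  target <- setdiff(target, unlist(lapply(
    c("--threshold", "--voxel", "--width", "--height", "--seed",
      "--open-iterations", "--out", "--overlay"),
    function(f) cli_opt(args, f, n = if (f == "--seed") 2L else 1L))))
  if (length(target) != 1L) { message("analyze needs one image"); return(2L) }
  cfg <- cli_config(args)
  seed <- cli_opt(args, "--seed", NULL, n = 2L)
  if (!is.null(seed)) seed <- as.integer(seed)
  res <- analyze_scan(target, cfg, seed)
  out <- cli_opt(args, "--out", "results.csv")
  write.csv(dplyr::bind_cols(tibble::tibble(path = target),
                             tibble::as_tibble(res)),
            out, row.names = FALSE)
  overlay <- cli_opt(args, "--overlay")
  if (!is.null(overlay)) {
    img <- if (is.character(target) && tolower(tools::file_ext(target)) == "raw") {
      read_raw(target, image_geometry(cfg$width, cfg$height, cfg$voxel_size))
    } else read_scan(target, cfg$voxel_size)
    render_overlay(img, res, overlay)
  }
  message("wrote ", out)
  0L
}

cli_batch <- function(args) {
  target <- args[!startsWith(args, "--")]
  target <- setdiff(target, unlist(lapply(
    c("--threshold", "--voxel", "--width", "--height", "--out"),
    function(f) cli_opt(args, f))))
  if (length(target) != 1L) { message("batch needs one manifest"); return(2L) }
  cfg <- cli_config(args)
  res <- analyze_batch(target, cfg)
  out <- cli_opt(args, "--out", "results.csv")
  write.csv(res, out, row.names = FALSE)
  errs <- attr(res, "errors")
  message("wrote ", out, " (", nrow(res), " ok, ",
          if (is.null(errs)) 0L else nrow(errs), " failed)")
  if (!is.null(errs) && nrow(errs) > 0L) 1L else 0L
}

cli_phantom <- function(args) {
  shape <- cli_opt(args, "--shape", "circular_annulus")
  v <- as.numeric(cli_opt(args, "--voxel", 0.5))
  W <- as.integer(cli_opt(args, "--width", 128))
  H <- as.integer(cli_opt(args, "--height", 128))
  seed <- as.integer(cli_opt(args, "--random-seed", 1))
  ph <- build_phantom(phantom_spec(shape = shape, seed = seed),
                      image_geometry(W, H, v))
  raw_out <- cli_opt(args, "--out-raw", "phantom.raw")
  write_raw(ph$image, raw_out)
  truth_out <- cli_opt(args, "--out-truth", "phantom_truth.json")
  jsonlite::write_json(as.list(ph$truth), truth_out, auto_unbox = TRUE,
                       digits = NA)
  preview <- cli_opt(args, "--out-preview")
  if (!is.null(preview)) {
    png::writePNG(ph$image$values / 65535, preview)
  }
  message("wrote ", raw_out, " and ", truth_out)
  0L
}

cli_compare <- function(args) {
  target <- args[!startsWith(args, "--")]
  target <- setdiff(target, unlist(lapply(c("--outcomes", "--out"),
                                          function(f) cli_opt(args, f))))
  if (length(target) != 1L) { message("compare needs one table"); return(2L) }
  outcomes <- cli_opt(args, "--outcomes")
  if (is.null(outcomes)) { message("--outcomes is required"); return(2L) }
  outcomes <- strsplit(outcomes, ",")[[1L]]
  tab <- read.csv(target)
  rep <- compare_cohorts(tab, outcomes, adjust = !"--no-adjust" %in% args)
  out <- cli_opt(args, "--out", "report.csv")
  write.csv(rep, out, row.names = FALSE)
  message("wrote ", out)
  0L
}

cli_render <- function(args) {
  target <- args[!startsWith(args, "--")]
  target <- setdiff(target, unlist(lapply(
    c("--threshold", "--voxel", "--width", "--height", "--out"),
    function(f) cli_opt(args, f))))
  if (length(target) != 1L) { message("render needs one image"); return(2L) }
  cfg <- cli_config(args)
  img <- if (tolower(tools::file_ext(target)) == "raw") {
    read_raw(target, image_geometry(cfg$width, cfg$height, cfg$voxel_size))
  } else read_scan(target, cfg$voxel_size)
  res <- analyze_scan(img, cfg)
  out <- cli_opt(args, "--out", "overlay.png")
  render_overlay(img, res, out)
  message("wrote ", out)
  0L
}
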