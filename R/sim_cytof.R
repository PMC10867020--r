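# Synthetic mass-cytometry (CyTOF) ion-count generator.

#' Generate a synthetic CyTOF ion-count table
#'
#' Per-marker ion counts are log-normal; each population applies its
#' configured log2 shift multiplicatively. Ground-truth shifts are attached.
#'
#' @param cfg a [sim_config()]; see the `cytof` sub-config.
#' @return list of class `ion_table`: `counts` (cells x markers),
#'   `population` (per cell), `patient`, and attribute `ground_truth` with
#'   the planted shift matrix and seed.
#' @export
gen_cytof_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cy <- cfg$cytof
  if (length(cy$populations) < 2L)
    abort("need at least 2 CyTOF populations")
  n_cells <- sum(cy$populations)
  pops <- rep(names(cy$populations), times = cy$populations)
  with_seed(cfg$seed + 404L, {
    counts <- matrix(0, n_cells, length(cy$markers),
                     dimnames = list(sprintf("event_%05d", seq_len(n_cells)),
                                     cy$markers))
    for (p in names(cy$populations)) {
      rows <- which(pops == p)
      for (mk in cy$markers) {
        mu <- cy$base_meanlog + cy$shifts[mk, p] * log(2)
        counts[rows, mk] <- rlnorm(length(rows), mu, cy$sdlog)
      }
    }
  })
  structure(list(counts = counts, population = pops,
                 patient = rep("sim1", n_cells)),
            class = "ion_table",
            ground_truth = list(shifts = cy$shifts, seed = cfg$seed))
}

#' Write an ion table as CSV (+ truth JSON)
#'
#' @param t an `ion_table`.
#' @param dir output directory.
#' @return Invisibly, the directory.
#' @export
write_sim_cytof <- function(t, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(event = rownames(t$counts), population = t$population,
                   patient = t$patient, t$counts, check.names = FALSE)
  write.csv(df, file.path(dir, "cytof_ions.csv"), row.names = FALSE)
  gt <- attr(t, "ground_truth")
  jsonlite::write_json(list(shifts = as.data.frame(gt$shifts),
                            shift_rows = rownames(gt$shifts),
                            seed = gt$seed),
                       file.path(dir, "cytof_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
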