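# Matrix-bundle directory format:
#   index.csv  with columns species_id, matrix_file, P, sociality,
#              body_mass_g, wild, unmanipulated, extant
#   <id>.A.csv / <id>.U.csv / <id>.F.csv  one CSV per sub-matrix,
#              stage labels as header row

#' Write a set of species records as a matrix bundle
#'
#' @param records List of species records (each with elements `species_id`,
#'   `mpm`, `sociality`, `body_mass_g`).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the path to `index.csv`.
#' @export
write_matrix_bundle <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- do.call(rbind, lapply(records, function(r) {
    m <- r$mpm
    data.frame(species_id = r$species_id,
               matrix_file = paste0(r$species_id, ".A.csv"),
               P = m$P,
               sociality = as.character(r$sociality),
               body_mass_g = r$body_mass_g,
               wild = !m$captive,
               unmanipulated = !m$treatment,
               extant = m$extant,
               stringsAsFactors = FALSE)
  }))
  for (r in records) {
    m <- r$mpm
    for (part in c("A", "U", "F")) {
      M <- m[[paste0("mat", part)]]
      df <- as.data.frame(M)
      names(df) <- m$stage_labels
      utils::write.csv(df, file.path(dir, paste0(r$species_id, ".", part, ".csv")),
                       row.names = FALSE)
    }
  }
  path <- file.path(dir, "index.csv")
  utils::write.csv(idx, path, row.names = FALSE)
  invisible(path)
}

#' Read a matrix bundle into a list of species records
#'
#' @param dir Directory containing `index.csv` and per-species matrix CSVs.
#' @return List of species records mirroring [write_matrix_bundle()] input.
#' @export
read_matrix_bundle <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(idx)), function(k) {
    row <- idx[k, ]
    read_part <- function(part) {
      f <- file.path(dir, paste0(row$species_id, ".", part, ".csv"))
      df <- utils::read.csv(f, check.names = FALSE)
      M <- as.matrix(df)
      rownames(M) <- colnames(M)
      M
    }
    A <- read_part("A"); U <- read_part("U"); F_ <- read_part("F")
    m <- validate_mpm(matU = U, matF = F_, matA = A, P = row$P,
                      stage_labels = colnames(A), species_id = row$species_id,
                      treatment = !row$unmanipulated, captive = !row$wild,
                      extant = row$extant)
    list(species_id = row$species_id, mpm = m,
         sociality = as_sociality(row$sociality),
         body_mass_g = row$body_mass_g,
         log_body_mass = log(row$body_mass_g))
  })
}

#' Write a per-species trait table as CSV
#'
#' Columns are `species_id` followed by the 11 life-history traits in
#' canonical order; missing values are written as empty cells.
#'
#' @param traits Data frame as returned by stacking [compute_all_traits()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trait_table <- function(traits, path) {
  cols <- c("species_id", trait_names())
  utils::write.csv(traits[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
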