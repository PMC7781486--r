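# Circuit designs, enumeration, and truth-table (ideal) output vectors.
#
# A 2-input BLADE circuit assigns one of four genes (STOP, GFP, mCherry,
# GFPmCherry) to each of the four DNA addresses Z00, Z10, Z01, Z11. The
# address subscripts encode the (Cre, Flp) input pair: Z00 is reached with no
# input, Z10 with Cre only, Z01 with Flp only and Z11 with both.

#' The four BLADE output genes
#'
#' Lookup table of the four genes that can occupy a BLADE address and the
#' fluorescent reporters each expresses. `STOP` expresses neither reporter,
#' `GFPmCherry` expresses both, `GFP` and `mCherry` exactly one each.
#'
#' @return A tibble with columns `gene`, `expresses_gfp`, `expresses_mcherry`.
#' @examples
#' blade_genes()
#' @export
blade_genes <- function() {
  tibble::tibble(
    gene = c("STOP", "GFP", "mCherry", "GFPmCherry"),
    expresses_gfp = c(FALSE, TRUE, FALSE, TRUE),
    expresses_mcherry = c(FALSE, FALSE, TRUE, TRUE)
  )
}

# Canonical address order; subscripts are the (Cre, Flp) input pair.
blade_addresses <- function() c("Z00", "Z10", "Z01", "Z11")

check_genes <- function(genes) {
  if (length(genes) != 4L) {
    stop("a circuit design is an ordered assignment of 4 genes (Z00, Z10, Z01, Z11), got ",
         length(genes), call. = FALSE)
  }
  genes <- as.character(genes)
  bad <- setdiff(genes, blade_genes()$gene)
  if (length(bad) > 0L) {
    stop("unknown gene(s): ", paste(bad, collapse = ", "),
         " (valid: STOP, GFP, mCherry, GFPmCherry)", call. = FALSE)
  }
  genes
}

#' Ideal (truth-table) output vector of a circuit
#'
#' Derives the 8-dimensional ideal "% cells ON" vector of a circuit design.
#' Entries are ordered address-major with a (GFP, mCherry) pair per address:
#' `[GFP@Z00, mCherry@Z00, GFP@Z10, mCherry@Z10, GFP@Z01, mCherry@Z01,
#' GFP@Z11, mCherry@Z11]`. Each entry is 100 when the gene at that address
#' expresses the reporter and 0 otherwise. The attribute `n_fluorescent`
#' counts the entries equal to 100 (the divisor of the adapted angular
#' metric); it is 0 only for the all-STOP circuit.
#'
#' @param genes Character vector of length 4: the genes at (Z00, Z10, Z01,
#'   Z11), each one of `"STOP"`, `"GFP"`, `"mCherry"`, `"GFPmCherry"`.
#' @return Numeric vector of length 8 of 0/100 values with attribute
#'   `n_fluorescent`.
#' @examples
#' ideal_vector(c("GFPmCherry", "GFP", "STOP", "GFP"))
#' @export
ideal_vector <- function(genes) {
  genes <- check_genes(genes)
  tab <- blade_genes()
  idx <- match(genes, tab$gene)
  v <- as.numeric(rbind(tab$expresses_gfp[idx], tab$expresses_mcherry[idx])) * 100
  structure(v, n_fluorescent = as.integer(sum(v > 0)))
}

#' Enumerate all 2-input BLADE circuit designs
#'
#' Generates the full set of 4^4 = 256 assignments of the four genes to the
#' four addresses, in a fixed, reproducible order: base-4 counting with digit
#' order (Z00, Z10, Z01, Z11) and gene order (STOP, GFP, mCherry,
#' GFPmCherry). The all-STOP design (circuit_id 1) prescribes no function and
#' is excluded by default, leaving 255 circuits.
#'
#' @param include_trivial Keep the all-STOP circuit? Default `FALSE`.
#' @return A tibble with one row per circuit: `circuit_id`, `gene_Z00` ..
#'   `gene_Z11`, the ideal vector as `ideal_v1` .. `ideal_v8`, and
#'   `n_fluorescent`.
#' @examples
#' nrow(blade_circuits())               # 255
#' nrow(blade_circuits(TRUE))           # 256
#' @export
blade_circuits <- function(include_trivial = FALSE) {
  genes <- blade_genes()$gene
  grid <- expand.grid(
    gene_Z11 = genes, gene_Z01 = genes, gene_Z10 = genes, gene_Z00 = genes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("gene_Z00", "gene_Z10", "gene_Z01", "gene_Z11")]
  out <- tibble::as_tibble(grid)
  out$circuit_id <- seq_len(nrow(out))
  ideals <- t(vapply(
    seq_len(nrow(out)),
    function(i) {
      v <- ideal_vector(unlist(out[i, 1:4], use.names = FALSE))
      c(v, attr(v, "n_fluorescent"))
    },
    numeric(9)
  ))
  colnames(ideals) <- c(paste0("ideal_v", 1:8), "n_fluorescent")
  out <- dplyr::bind_cols(out, tibble::as_tibble(ideals))
  out$n_fluorescent <- as.integer(out$n_fluorescent)
  out <- dplyr::select(out, "circuit_id", dplyr::everything())
  if (!include_trivial) {
    out <- dplyr::filter(out, .data$n_fluorescent > 0L)
  }
  out
}

#' Read or write a circuit table
#'
#' CSV round-trip for the table produced by [blade_circuits()]. Comma
#' separated, UTF-8, header row, one ideal-vector entry per column.
#'
#' @param circuits A circuit tibble from [blade_circuits()].
#' @param path File path.
#' @return `write_circuit_table()` returns `path` invisibly;
#'   `read_circuit_table()` returns the circuit tibble.
#' @export
write_circuit_table <- function(circuits, path) {
  readr::write_csv(circuits, path)
  invisible(path)
}

#' @rdname write_circuit_table
#' @export
read_circuit_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    circuit_id = readr::col_integer(),
                    n_fluorescent = readr::col_integer(),
                    .default = readr::col_guess()
                  ))
}

# Extract the 4 genes of one circuit row as a character vector.
circuit_genes <- function(circuit_row) {
  unlist(circuit_row[paste0("gene_", blade_addresses())], use.names = FALSE)
}
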