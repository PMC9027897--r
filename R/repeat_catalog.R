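#' Is a repeat name an Alu element?
#'
#' Alu elements are recognised by the exact name prefix `"Alu"`. Free Alu
#' monomers (FLAM/FRAM) and other SINEs deliberately do not match, so a
#' catalog built from a RepeatMasker track contains only the three canonical
#' Alu families.
#'
#' @param name Character vector of repeat names.
#' @return Logical vector.
#' @examples
#' is_alu(c("AluSx1", "MIRb", "FLAM_C"))
#' @export
is_alu <- function(name) {
  stopifnot(is.character(name), all(nzchar(name)))
  startsWith(name, "Alu")
}

#' Classify an Alu subfamily into its family
#'
#' The family is determined by the character following `"Alu"`: J (oldest),
#' S, or Y (youngest).
#'
#' @param subfamily Character vector of Alu subfamily names (e.g. "AluSx1").
#' @return Character vector with values in `AluJ`, `AluS`, `AluY`.
#' @examples
#' alu_family(c("AluSx1", "AluJo", "AluY"))
#' @export
alu_family <- function(subfamily) {
  if (!all(is_alu(subfamily))) {
    stop("not an Alu subfamily name: ",
         paste(subfamily[!is_alu(subfamily)], collapse = ", "))
  }
  letter <- substr(subfamily, 4L, 4L)
  fam <- c(J = "AluJ", S = "AluS", Y = "AluY")[letter]
  if (anyNA(fam)) {
    stop("cannot classify Alu family for: ",
         paste(unique(subfamily[is.na(fam)]), collapse = ", "))
  }
  unname(fam)
}

#' Build the Alu element catalog from a repeat track
#'
#' Filters a repeat track (from [read_bed()] or
#' [read_gtf()] with the `repeatmasker` dialect) down to Alu-named records,
#' classifies each into its family and sorts by (chromosome, start) with
#' lexicographic chromosome order. Non-Alu records are silently removed
#' (count reported via a message); Alu-named records whose family letter is
#' not J/S/Y are dropped with a warning.
#'
#' @param records A `GRanges` with a `name` metadata column.
#' @return A `GRanges` catalog with metadata columns `subfamily` and `family`.
#' @export
build_catalog <- function(records) {
  if (is.null(records$name) && !is.null(records$subfamily)) {
    records$name <- records$subfamily
  }
  if (is.null(records$name)) stop("repeat records must carry a 'name' column")
  nm <- as.character(records$name)
  alu <- !is.na(nm) & is_alu(ifelse(is.na(nm) | !nzchar(nm), "x", nm))
  n_dropped <- sum(!alu)
  if (n_dropped > 0L) {
    message(n_dropped, " non-Alu record(s) filtered from repeat track")
  }
  records <- records[alu]
  nm <- nm[alu]
  letter <- substr(nm, 4L, 4L)
  ok <- letter %in% c("J", "S", "Y")
  if (any(!ok)) {
    warning(sum(!ok), " Alu-named record(s) with unrecognised family letter ",
            "dropped: ", paste(unique(nm[!ok]), collapse = ", "))
    records <- records[ok]
    nm <- nm[ok]
  }
  out <- GenomicRanges::granges(records)
  out$subfamily <- nm
  out$family <- if (length(nm)) alu_family(nm) else character(0)
  ord <- order(as.character(GenomicRanges::seqnames(out)),
               GenomicRanges::start(out))
  out[ord]
}

#' Write an Alu catalog as BED6 (name = subfamily)
#'
#' @param catalog A catalog from [build_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  gr <- GenomicRanges::granges(catalog)
  gr$name <- catalog$subfamily
  gr$score <- 0
  write_bed(gr, path)
}
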