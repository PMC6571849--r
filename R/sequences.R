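#' Nucleotide sequence
#'
#' A validated single-stranded DNA sequence over the alphabet ACGT.
#' Ambiguity codes and U are rejected: the model is defined for fully
#' specified DNA only.
#'
#' @param seq Character scalar over `{A,C,G,T}` (lower case is accepted and
#'   upper-cased). Must be non-empty.
#' @param id Text label for the sequence.
#' @return An object of class `nt_seq` with fields `id` and `seq`.
#' @examples
#' nt_seq("ACGT", id = "arm1")
#' @export
nt_seq <- function(seq, id = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop_lasso("`seq` must be a single character string", "invalid_sequence")
  }
  seq <- toupper(seq)
  if (nchar(seq) == 0L) {
    stop_lasso("sequence must be non-empty", "invalid_sequence")
  }
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (bad[1] != -1L) {
    stop_lasso(
      sprintf("sequence '%s' contains non-ACGT characters at position(s) %s",
              id, paste(bad, collapse = ", ")),
      "invalid_sequence", positions = as.integer(bad)
    )
  }
  structure(list(id = as.character(id), seq = seq), class = "nt_seq")
}

#' @export
print.nt_seq <- function(x, ...) {
  s <- x$seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<nt_seq> %s (%d nt): %s\n", x$id, nchar(x$seq), s))
  invisible(x)
}

as_seq_string <- function(x, name, allow_empty = FALSE) {
  if (inherits(x, "nt_seq")) return(x$seq)
  if (is.character(x) && length(x) == 1L && !is.na(x)) {
    x <- toupper(x)
    if (nchar(x) == 0L) {
      if (allow_empty) return(x)
      stop_lasso(sprintf("`%s` must be non-empty", name), "invalid_sequence")
    }
    if (grepl("[^ACGT]", x)) {
      stop_lasso(sprintf("`%s` contains non-ACGT characters", name), "invalid_sequence")
    }
    return(x)
  }
  stop_lasso(sprintf("`%s` must be a string or nt_seq", name), "invalid_sequence")
}

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar or [nt_seq()].
#' @return Character scalar, the reverse complement.
#' @export
reverse_complement <- function(seq) {
  s <- as_seq_string(seq, "seq")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' LASSO probe specification
#'
#' A LASSO (long-adapter single-stranded oligonucleotide) probe is a linear
#' ssDNA molecule: an extension arm at the 5' end, a ligation arm at the 3'
#' end, and an adapter of user-defined length between them. With a zero-length
#' adapter the construct degenerates to a classical molecular inversion probe
#' (MIP).
#'
#' @param extension_arm,ligation_arm Arm sequences (string or [nt_seq()]);
#'   must be non-empty.
#' @param adapter Adapter sequence; may be the empty string (MIP-like case).
#' @param id Probe label.
#' @return Object of class `probe_spec` with fields `extension_arm`,
#'   `ligation_arm`, `adapter`, `adapter_length`, `id`.
#' @export
probe_spec <- function(extension_arm, ligation_arm, adapter = "", id = "probe") {
  ext <- as_seq_string(extension_arm, "extension_arm")
  lig <- as_seq_string(ligation_arm, "ligation_arm")
  ada <- as_seq_string(adapter, "adapter", allow_empty = TRUE)
  structure(
    list(extension_arm = ext, ligation_arm = lig, adapter = ada,
         adapter_length = nchar(ada), id = as.character(id)),
    class = "probe_spec"
  )
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("<probe_spec> %s: ext %d nt | adapter %d nt | lig %d nt (total %d nt)\n",
              x$id, nchar(x$extension_arm), x$adapter_length,
              nchar(x$ligation_arm), probe_length(x)))
  invisible(x)
}

#' @rdname probe_spec
#' @param spec A `probe_spec`.
#' @export
probe_length <- function(spec) {
  stopifnot(inherits(spec, "probe_spec"))
  nchar(spec$extension_arm) + spec$adapter_length + nchar(spec$ligation_arm)
}

#' Assemble the full probe sequence
#'
#' Concatenates extension arm, adapter and ligation arm, with the arms at the
#' 5' and 3' termini respectively.
#'
#' @param spec A [probe_spec()].
#' @return An [nt_seq()] of length `|ext| + adapter_length + |lig|`.
#' @examples
#' build_probe(probe_spec("ACGT", "TTTT", adapter = "AAA"))
#' @export
build_probe <- function(spec) {
  if (!inherits(spec, "probe_spec")) {
    stop_lasso("`spec` must be a probe_spec", "invalid_spec")
  }
  nt_seq(paste0(spec$extension_arm, spec$adapter, spec$ligation_arm), id = spec$id)
}

#' Target specification
#'
#' The target is a linear ssDNA fragment carrying two disjoint sites whose
#' sequences are the reverse complements of the probe's extension and ligation
#' arms. Site intervals are 0-based and half-open, `c(start, end)`.
#'
#' @param sequence Target sequence (string or [nt_seq()]).
#' @param ext_site,lig_site Integer vectors `c(start, end)`, 0-based half-open
#'   intervals on the target; must lie within the sequence and not overlap.
#' @param id Target label.
#' @return Object of class `target_spec`.
#' @export
target_spec <- function(sequence, ext_site, lig_site, id = "target") {
  seq <- as_seq_string(sequence, "sequence")
  n <- nchar(seq)
  chk_site <- function(site, name) {
    if (!is.numeric(site) || length(site) != 2L || any(site != round(site))) {
      stop_lasso(sprintf("`%s` must be an integer c(start, end)", name), "invalid_spec")
    }
    site <- as.integer(site)
    if (site[1] < 0L || site[2] > n || site[1] >= site[2]) {
      stop_lasso(sprintf("`%s` [%d, %d) is outside the target bounds [0, %d)",
                         name, site[1], site[2], n), "invalid_spec")
    }
    site
  }
  ext_site <- chk_site(ext_site, "ext_site")
  lig_site <- chk_site(lig_site, "lig_site")
  if (max(ext_site[1], lig_site[1]) < min(ext_site[2], lig_site[2])) {
    stop_lasso("ext_site and lig_site must be disjoint", "invalid_spec")
  }
  structure(list(sequence = seq, ext_site = ext_site, lig_site = lig_site,
                 id = as.character(id)),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("<target_spec> %s: %d nt, ext site [%d,%d), lig site [%d,%d)\n",
              x$id, nchar(x$sequence), x$ext_site[1], x$ext_site[2],
              x$lig_site[1], x$lig_site[2]))
  invisible(x)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Map the designed arm-target base pairs
#'
#' Enumerates, for each arm, every complementary base pair between the probe
#' arm and its target site. Pairing is antiparallel: the arm read 5'->3' maps
#' onto the site read 3'->5'. Indices are 0-based: `probe_index` refers to the
#' assembled full probe (extension arm first), `target_index` to the target
#' sequence.
#'
#' @param probe A [probe_spec()].
#' @param target A [target_spec()].
#' @return A tibble with columns `arm` ("extension"/"ligation"),
#'   `probe_index`, `target_index`, `probe_base`, `target_base`, one row per
#'   designed base pair.
#' @export
find_arm_complements <- function(probe, target) {
  if (!inherits(probe, "probe_spec")) stop_lasso("`probe` must be a probe_spec", "invalid_spec")
  if (!inherits(target, "target_spec")) stop_lasso("`target` must be a target_spec", "invalid_spec")
  lp <- probe_length(probe)
  tchars <- strsplit(target$sequence, "")[[1]]

  one_arm <- function(arm_seq, site, arm_name, probe_offset) {
    m <- nchar(arm_seq)
    if (site[2] - site[1] != m) {
      stop_lasso(sprintf("%s arm is %d nt but its target site [%d,%d) spans %d nt",
                         arm_name, m, site[1], site[2], site[2] - site[1]),
                 "site_mismatch")
    }
    a <- strsplit(arm_seq, "")[[1]]
    ti <- (site[2] - 1L):site[1]              # antiparallel: arm 5'->3' vs site 3'->5'
    tibble(
      arm = arm_name,
      probe_index = probe_offset + 0:(m - 1L),
      target_index = ti,
      probe_base = a,
      target_base = tchars[ti + 1L]
    )
  }

  out <- dplyr::bind_rows(
    one_arm(probe$extension_arm, target$ext_site, "extension", 0L),
    one_arm(probe$ligation_arm, target$lig_site, "ligation",
            lp - nchar(probe$ligation_arm))
  )
  bad <- out$target_base != unname(COMPLEMENT[out$probe_base])
  if (any(bad)) {
    b <- out[bad, ]
    stop_lasso(
      sprintf(
        "non-complementary arm/site base pair(s): %s",
        paste(sprintf("%s arm probe[%d]=%s vs target[%d]=%s",
                      b$arm, b$probe_index, b$probe_base,
                      b$target_index, b$target_base),
              collapse = "; ")
      ),
      "arm_mismatch",
      mismatches = b
    )
  }
  out
}
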