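# Physical constants and residue chemistry shared by all modules.
#
# Monoisotopic masses are hard-coded to >= 6 decimals so that every mass in
# the package is bit-reproducible across platforms; natural abundances are
# IUPAC representative values. Both are overridable through a plain-text
# key=value config (see isotope_constants()).

.ISOCHASE_MASSES <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.ISOCHASE_PROTON <- 1.00727646

# 13C - 12C mass difference; sets the isotope channel spacing (divided by z).
.ISOCHASE_C13_DEFECT <- 1.003355

# Per-element relative abundance by nucleon shift (index 1 = shift 0).
.ISOCHASE_ABUNDANCES <- list(
  C = c(1 - 0.0107, 0.0107),
  H = c(1 - 0.000115, 0.000115),
  N = c(1 - 0.00364, 0.00364),
  O = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
  S = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425)
)

# Residue (monomer) compositions: free amino acid minus one water.
.ISOCHASE_RESIDUES <- list(
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0)
)

.ISOCHASE_WATER <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

#' Isotope and residue constants
#'
#' Bundles the monoisotopic atomic masses, natural isotope abundances,
#' proton mass, the 13C mass defect, and the amino-acid residue composition
#' table used throughout the package. An optional plain-text config file
#' (one `key=value` per line, `#` comments allowed) overrides individual
#' entries, which permits exact reproduction of results computed under an
#' alternative abundance table.
#'
#' Recognized keys:
#' \describe{
#'   \item{`mass.<El>`}{monoisotopic mass of element `<El>` (Da)}
#'   \item{`abundance.<El>.<j>`}{relative abundance of the isotope `j`
#'     nucleons above the lightest (`j >= 0`); the shift-0 abundance is
#'     recomputed so the element's abundances sum to 1}
#'   \item{`proton`}{proton mass (Da)}
#' }
#'
#' @param config optional path to a key=value override file.
#' @return A list with elements `masses`, `abundances`, `proton`,
#'   `c13_defect`, `residues`, `water`.
#' @examples
#' const <- isotope_constants()
#' const$abundances$C[2]  # natural 13C abundance
#' @export
isotope_constants <- function(config = NULL) {
  const <- list(
    masses = .ISOCHASE_MASSES,
    abundances = .ISOCHASE_ABUNDANCES,
    proton = .ISOCHASE_PROTON,
    c13_defect = .ISOCHASE_C13_DEFECT,
    residues = .ISOCHASE_RESIDUES,
    water = .ISOCHASE_WATER
  )
  if (is.null(config)) {
    return(const)
  }
  if (!file.exists(config)) {
    stop("isotope config file not found: ", config)
  }
  lines <- readLines(config, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- as.numeric(trimws(kv[2]))
    if (is.na(val)) stop("non-numeric config value in line: ", ln)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (parts[1] == "mass" && length(parts) == 2) {
      if (!parts[2] %in% names(const$masses)) {
        stop("unsupported element in config: ", parts[2])
      }
      const$masses[[parts[2]]] <- val
    } else if (parts[1] == "abundance" && length(parts) == 3) {
      el <- parts[2]
      j <- as.integer(parts[3])
      if (!el %in% names(const$abundances)) {
        stop("unsupported element in config: ", el)
      }
      ab <- const$abundances[[el]]
      if (j + 1L > length(ab)) {
        ab <- c(ab, numeric(j + 1L - length(ab)))
      }
      ab[j + 1L] <- val
      if (j > 0L) ab[1L] <- 1 - sum(ab[-1L])
      if (any(ab < 0)) stop("config abundances for ", el, " exceed 1")
      const$abundances[[el]] <- ab
    } else if (key == "proton") {
      const$proton <- val
    } else {
      stop("unrecognized config key: ", key)
    }
  }
  const
}
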