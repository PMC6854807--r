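#' Kors regression matrix
#'
#' Fixed 3 x 8 regression matrix reconstructing the orthogonal X, Y, Z
#' leads from the eight independent standard leads (I, II, V1-V6).
#' Coefficients from Kors et al., Eur Heart J 1990;11:1083-92 (Table:
#' "regression" transform).  Limb leads III, aVR, aVL, aVF are linear
#' combinations of I and II and carry no extra information, so the matrix
#' ignores them.
#'
#' @format numeric matrix, rows X/Y/Z, columns I, II, V1-V6, unitless.
#' @export
KORS_MATRIX <- matrix(
  c(# I      II     V1     V2     V3     V4     V5     V6
     0.38, -0.07, -0.13,  0.05, -0.01,  0.14,  0.06,  0.54,  # X
    -0.07,  0.93,  0.06, -0.02, -0.05,  0.06, -0.17,  0.13,  # Y
     0.11, -0.23, -0.43, -0.06, -0.14, -0.20, -0.11,  0.31), # Z
  nrow = 3, byrow = TRUE,
  dimnames = list(c("X", "Y", "Z"),
                  c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")))

#' Standard 12-lead ordering used throughout the package
#' @export
LEAD_NAMES_12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
                   "V1", "V2", "V3", "V4", "V5", "V6")

# Moore-Penrose right-inverse of the Kors matrix (8 x 3):
# KORS_MATRIX %*% kors_right_inverse() == identity, so a dipole mapped to
# the 8 independent leads through it is recovered exactly by the forward
# transform.  Used by the synthetic ECG generator.
kors_right_inverse <- function() {
  K <- KORS_MATRIX
  t(K) %*% solve(K %*% t(K))
}

#' Transform a 12-lead ECG to orthogonal XYZ leads (Kors)
#'
#' Applies the Kors regression transform to the eight independent leads
#' (I, II, V1-V6).  The derived limb leads III, aVR, aVL, aVF are ignored.
#'
#' @param record an `ecg12_record` (see [generate_ecg12()]) or a numeric
#'   matrix samples x 12 in microvolts with columns ordered as
#'   [LEAD_NAMES_12].
#' @return numeric matrix samples x 3 with columns X, Y, Z, in microvolts.
#' @export
kors_transform <- function(record) {
  sig <- if (inherits(record, "ecg12_record")) record$signal else record
  if (!is.matrix(sig) || ncol(sig) != 12L)
    stop("expected a samples x 12 signal matrix")
  cn <- colnames(sig)
  if (is.null(cn)) cn <- LEAD_NAMES_12
  need <- colnames(KORS_MATRIX)
  idx <- match(need, cn)
  if (anyNA(idx))
    stop("missing lead(s): ", paste(need[is.na(idx)], collapse = ", "))
  bad <- need[vapply(idx, function(j) anyNA(sig[, j]) || any(!is.finite(sig[, j])),
                     logical(1))]
  if (length(bad))
    stop("non-finite samples in lead(s): ", paste(bad, collapse = ", "))
  xyz <- sig[, idx, drop = FALSE] %*% t(KORS_MATRIX)
  colnames(xyz) <- c("X", "Y", "Z")
  xyz
}
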