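# Condition helpers: typed errors so callers (and the CLI) can map failure
# classes to exit codes.
lgStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "lesiongraph_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
validationError <- function(fmt, ...) lgStop("lesiongraph_validation_error", fmt, ...)
formatError     <- function(fmt, ...) lgStop("lesiongraph_format_error", fmt, ...)
registrationError <- function(fmt, ...) lgStop("lesiongraph_registration_error", fmt, ...)
capabilityError <- function(fmt, ...) lgStop("lesiongraph_capability_error", fmt, ...)
degenerateError <- function(fmt, ...) lgStop("lesiongraph_degenerate_error", fmt, ...)

# Affine voxel<->physical mapping. Voxel indices are zero-based here;
# phys = origin + direction %*% diag(spacing) %*% idx0.
affineOf <- function(vol) {
  A <- vol@direction %*% diag(vol@spacing)
  list(A = A, Ainv = solve(A), b = vol@origin)
}

# idx0: n x 3 zero-based voxel indices -> n x 3 physical points (mm)
voxelToPhys <- function(vol, idx0) {
  af <- affineOf(vol)
  sweep(idx0 %*% t(af$A), 2L, af$b, "+")
}

# points: n x 3 physical -> n x 3 zero-based continuous voxel indices
physToVoxel <- function(vol, points) {
  af <- affineOf(vol)
  sweep(points, 2L, af$b, "-") %*% t(af$Ainv)
}

sameGeometry <- function(a, b, tol = 1e-6) {
  all(dim(a@voxels) == dim(b@voxels)) &&
    max(abs(a@spacing - b@spacing)) < tol &&
    max(abs(a@origin - b@origin)) < tol &&
    max(abs(a@direction - b@direction)) < tol
}

# Physical centroid (mm) of the TRUE voxels of a binary LabelVolume.
maskCentroid <- function(vol) {
  idx <- which(vol@voxels > 0)
  if (!length(idx))
    degenerateError("mask is empty: cannot compute a centroid")
  d <- dim(vol@voxels)
  ijk <- arrayInd(idx, d) - 1L
  colMeans(voxelToPhys(vol, ijk))
}

# Seed scoping: run expr with a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
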