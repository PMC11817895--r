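#' Write / read a plan in the NIfTI + JSON fixture dialect
#'
#' The fixture dialect stores each volume (dose, structure masks) as a
#' float64 NIfTI file and all plan metadata in a `plan.json` sidecar:
#' prescription dose (Gy), fraction count, primary target, per-structure
#' roles, and the authoritative grid geometry (spacing mm, origin mm). The
#' sidecar, not the NIfTI header, is the authority for geometry, which keeps
#' the round trip bit-identical and free of NIfTI orientation dialects.
#' All lengths are mm, volumes cm^3, doses Gy.
#'
#' @param plan An [rt_plan()].
#' @param dir Directory to create/fill.
#' @return `write_plan_fixture()` returns the sidecar path invisibly;
#'   `read_plan_fixture()` returns an [rt_plan()].
#' @export
write_plan_fixture <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(
    RNifti::asNifti(plan$dose$values, pixdim = plan$dose$spacing,
                    datatype = "double"),
    file.path(dir, "dose.nii.gz")
  )
  structs <- purrr::map(plan$structures, function(s) {
    file <- sprintf("mask_%s.nii.gz", gsub("[^A-Za-z0-9_-]", "_", s$name))
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(s$mask), dim = dim(s$mask)),
                      pixdim = s$spacing, datatype = "uint8"),
      file.path(dir, file)
    )
    list(name = s$name, role = s$role, file = file)
  })
  sidecar <- list(
    format = "sbgrad-plan-fixture",
    units = list(length = "mm", dose = "Gy", volume = "cm3"),
    rx_dose_gy = plan$rx_dose,
    n_fractions = plan$n_fractions,
    primary_target = plan$primary_target,
    spacing_mm = plan$dose$spacing,
    origin_mm = plan$dose$origin,
    dose_file = "dose.nii.gz",
    structures = unname(structs)
  )
  path <- file.path(dir, "plan.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan_fixture
#' @param path The fixture directory or its `plan.json` sidecar.
#' @export
read_plan_fixture <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "plan.json")
  if (!file.exists(path)) abort(sprintf("No fixture sidecar at '%s'.", path))
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(meta$format, "sbgrad-plan-fixture")) {
    abort("Not an sbgrad plan fixture (missing format tag).")
  }
  dir <- dirname(path)
  vals <- as.array(RNifti::readNifti(file.path(dir, meta$dose_file)))
  dose <- dose_grid(vals, meta$spacing_mm, meta$origin_mm)
  structs <- purrr::pmap(meta$structures, function(name, role, file) {
    m <- as.array(RNifti::readNifti(file.path(dir, file)))
    structure_mask(m > 0, meta$spacing_mm, meta$origin_mm,
                   name = name, role = role)
  })
  rt_plan(dose, structs, meta$rx_dose_gy, meta$n_fractions,
          primary_target = meta$primary_target)
}
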