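#' Write and read trajectories
#'
#' Trajectories are stored as plain CSV (column `t`, then one column per
#' state coordinate, plus `state` for switching runs) with a JSON sidecar
#' (`<path>.json`) recording the step size, thinning, seed and model kind so
#' a run can be reproduced.
#'
#' @param traj an `mvt_trajectory` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(dt = attr(traj, "dt"), thin = attr(traj, "thin"),
               seed = attr(traj, "seed"), kind = attr(traj, "kind"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tr <- tibble::as_tibble(utils::read.csv(path))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    attr(tr, "dt") <- meta$dt
    attr(tr, "thin") <- meta$thin
    attr(tr, "seed") <- meta$seed
    attr(tr, "kind") <- meta$kind
  }
  class(tr) <- c("mvt_trajectory", class(tr))
  tr
}
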