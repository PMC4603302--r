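# Scheduling and job processing. Monitoring runs are placed on a
# homogeneous FIFO queue without priority ordering and processed with
# bounded concurrency: with a worker limit of two and four queued tasks,
# they are processed two at a time, in order of arrival. The scheduler is
# driven by an injectable clock, so timing behaviour is fully testable on a
# simulated clock.

resolve_schedule <- function(ws, name) {
  interval <- if (name %in% names(ws$settings$schedules)) {
    ws$settings$schedules[[name]]
  }
  if (is.null(interval) || is.na(interval)) {
    config_error(paste0("unknown schedule: ", name, " (configured: ",
                        toString(names(ws$settings$schedules)), ")"))
  }
  as.numeric(interval)
}

#' Agents due for a monitoring run
#'
#' An agent is due when its schedule interval has elapsed since its last
#' run (or it has never run). Order is stable registration order. Disabled
#' agents are never due.
#'
#' @param ws A [flux_workspace()].
#' @param now Current time (POSIXct); defaults to the workspace clock.
#' @param agents Agents to consider; defaults to all registered agents.
#' @return List of due `flux_agent` objects.
#' @export
due_agents <- function(ws, now = ws$clock(), agents = ws$agents) {
  Filter(function(ag) {
    if (!ag$enabled) return(FALSE)
    interval <- resolve_schedule(ws, ag$schedule)
    last <- ws$last_run[[ag$id]]
    is.null(last) || as.numeric(difftime(now, last, units = "secs")) >= interval
  }, agents)
}

#' A FIFO job queue
#'
#' Jobs enter in arrival order and are processed first-in-first-out. At most
#' one pending job is kept per agent: enqueueing an agent that already has a
#' queued job is a no-op, so a slow run never piles up duplicates.
#'
#' @return An object of class `flux_queue`.
#' @export
job_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$jobs <- list()
  q$counter <- 0L
  class(q) <- "flux_queue"
  q
}

#' @rdname job_queue
#' @param queue A [job_queue()].
#' @param agent_id Agent the job will monitor.
#' @param arrival Arrival time (numeric, seconds on the simulation clock).
#' @param service_time Simulated duration of the job, used by the trace.
#' @param work Optional zero-argument function executed when the job runs.
#' @return `enqueue_job` returns the job id, or `NA` if suppressed.
#' @export
enqueue_job <- function(queue, agent_id, arrival = 0, service_time = 0, work = NULL) {
  pending <- vapply(queue$jobs, function(j) {
    identical(j$agent_id, agent_id) && identical(j$state, "queued")
  }, TRUE)
  if (any(pending)) return(NA_character_)
  queue$counter <- queue$counter + 1L
  id <- sprintf("job-%06d", queue$counter)
  queue$jobs[[id]] <- list(id = id, agent_id = agent_id,
                           enqueued_at = as.numeric(arrival),
                           service_time = as.numeric(service_time),
                           work = work, state = "queued")
  id
}

#' Process queued jobs with bounded concurrency
#'
#' Dequeues jobs strictly in order of arrival and assigns each to the
#' earliest-free worker of a pool of `worker_limit` workers, so that at no
#' instant do more than `worker_limit` jobs run. Each job's work (typically
#' a full monitor-and-route pass) executes to completion when the job
#' starts; a failing job is marked failed and logged but never blocks the
#' queue. The returned trace records the start/end instants on the
#' simulation clock and the worker assignment for every job.
#'
#' @param queue A [job_queue()].
#' @param worker_limit Maximum simultaneously running jobs (>= 1).
#' @param ws Optional workspace, used only for logging job failures.
#' @return A data frame (the execution trace) with columns `job_id`,
#'   `agent_id`, `arrival`, `start`, `end`, `worker`, `state`, in start
#'   order.
#' @export
process_queue <- function(queue, worker_limit, ws = NULL) {
  if (worker_limit < 1L) config_error("worker_limit must be >= 1")
  jobs <- Filter(function(j) identical(j$state, "queued"), queue$jobs)
  jobs <- jobs[order(vapply(jobs, `[[`, 0, "enqueued_at"),
                     seq_along(jobs))]   # FIFO; ties broken by enqueue order
  free <- rep(0, worker_limit)
  rows <- vector("list", length(jobs))
  for (i in seq_along(jobs)) {
    job <- jobs[[i]]
    worker <- which.min(free)
    start <- max(job$enqueued_at, free[[worker]])
    end <- start + job$service_time
    free[[worker]] <- end
    state <- "done"
    if (!is.null(job$work)) {
      state <- tryCatch({ job$work(); "done" }, error = function(e) {
        if (!is.null(ws)) {
          flux_log(ws, "queue", paste0("agent:", job$agent_id),
                   paste0("job ", job$id, " failed: ", conditionMessage(e)),
                   "error")
        }
        "failed"
      })
    }
    queue$jobs[[job$id]]$state <- state
    rows[[i]] <- data.frame(job_id = job$id, agent_id = job$agent_id,
                            arrival = job$enqueued_at, start = start,
                            end = end, worker = worker, state = state,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(job_id = character(), agent_id = character(),
               arrival = numeric(), start = numeric(), end = numeric(),
               worker = integer(), state = character(), stringsAsFactors = FALSE)
}

#' Peak concurrency of an execution trace
#'
#' Maximum number of jobs simultaneously running over a trace, counting a
#' job as running on the half-open interval `[start, end)`.
#'
#' @param trace A trace from [process_queue()].
#' @return Integer.
#' @export
peak_concurrency <- function(trace) {
  if (!nrow(trace)) return(0L)
  pts <- sort(unique(trace$start))
  max(vapply(pts, function(t) sum(trace$start <= t & trace$end > t), 0L))
}

#' Run every due agent through the queue
#'
#' Convenience driver for one scheduler tick: enqueues all due agents (each
#' job is a full [run_agent()] pass) and processes the queue with the
#' configured worker limit.
#'
#' @param ws A [flux_workspace()].
#' @param now Tick time; defaults to the workspace clock.
#' @return The execution trace, invisibly.
#' @export
run_due <- function(ws, now = ws$clock()) {
  queue <- job_queue()
  for (ag in due_agents(ws, now)) {
    local({
      agent <- ag
      enqueue_job(queue, agent$id, work = function() run_agent(ws, agent))
    })
  }
  invisible(process_queue(queue, ws$settings$worker_limit, ws = ws))
}
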