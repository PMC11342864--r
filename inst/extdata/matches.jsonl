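{"match_id":"m00001","gamer_id":"g1","started_at":"2021-04-03T06:00:00Z","finished_at":"2021-04-03T06:34:01Z","kills":19,"deaths":13,"assists":4}
{"match_id":"m00002","gamer_id":"g1","started_at":"2021-04-03T06:55:24Z","finished_at":"2021-04-03T07:33:02Z","kills":14,"deaths":15,"assists":3}
{"match_id":"m00003","gamer_id":"g1","started_at":"2021-04-03T07:48:33Z","finished_at":"2021-04-03T08:27:40Z","kills":12,"deaths":13,"assists":1}
{"match_id":"m00004","gamer_id":"g1","started_at":"2021-04-03T08:49:32Z","finished_at":"2021-04-03T09:30:59Z","kills":17,"deaths":14,"assists":8}
{"match_id":"m00005","gamer_id":"g1","started_at":"2021-04-03T09:39:36Z","finished_at":"2021-04-03T10:14:17Z","kills":23,"deaths":13,"assists":5}
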