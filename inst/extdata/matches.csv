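match_id,gamer_id,started_at,finished_at,kills,deaths,assists
m00001,g1,2021-04-03T06:00:00Z,2021-04-03T06:34:01Z,19,13,4
m00002,g1,2021-04-03T06:55:24Z,2021-04-03T07:33:02Z,14,15,3
m00003,g1,2021-04-03T07:48:33Z,2021-04-03T08:27:40Z,12,13,1
m00004,g1,2021-04-03T08:49:32Z,2021-04-03T09:30:59Z,17,14,8
m00005,g1,2021-04-03T09:39:36Z,2021-04-03T10:14:17Z,23,13,5
m00006,g1,2021-04-03T10:39:11Z,2021-04-03T11:19:38Z,23,16,4
m00007,g1,2021-04-03T11:24:44Z,2021-04-03T12:02:09Z,16,17,2
m00008,g1,2021-04-03T12:27:49Z,2021-04-03T13:01:36Z,18,14,6
m00009,g1,2021-04-03T13:07:10Z,2021-04-03T13:40:10Z,21,14,2
m00010,g1,2021-04-03T13:44:17Z,2021-04-03T14:14:13Z,14,20,6
m00011,g1,2021-04-06T22:00:00Z,2021-04-06T22:36:37Z,21,18,7
m00012,g1,2021-04-06T22:49:20Z,2021-04-06T23:26:57Z,11,13,6
m00013,g1,2021-04-06T23:35:11Z,2021-04-07T00:13:51Z,15,17,6
m00014,g1,2021-04-07T00:25:38Z,2021-04-07T01:00:29Z,15,17,8
m00015,g1,2021-04-07T01:19:34Z,2021-04-07T01:53:10Z,22,13,4
m00016,g1,2021-04-07T02:08:22Z,2021-04-07T02:49:58Z,8,14,6
m00017,g1,2021-04-07T03:04:52Z,2021-04-07T03:41:55Z,30,21,2
m00018,g1,2021-04-07T03:50:30Z,2021-04-07T04:32:43Z,14,17,9
m00019,g1,2021-04-07T04:44:43Z,2021-04-07T05:29:07Z,18,20,7
m00020,g1,2021-04-07T05:37:52Z,2021-04-07T06:16:22Z,14,19,5
m00021,g1,2021-04-07T06:33:45Z,2021-04-07T07:08:59Z,12,14,6
m00022,g1,2021-04-07T07:12:39Z,2021-04-07T07:57:32Z,12,18,1
m00023,g1,2021-04-08T01:35:13Z,2021-04-08T02:09:13Z,23,20,0
m00024,g1,2021-04-08T02:17:10Z,2021-04-08T02:59:38Z,18,19,1
m00025,g1,2021-04-08T03:05:46Z,2021-04-08T03:43:24Z,17,12,2
m00026,g1,2021-04-08T03:50:06Z,2021-04-08T04:29:20Z,21,13,1
m00027,g1,2021-04-09T01:13:33Z,2021-04-09T01:51:33Z,17,24,3
m00028,g1,2021-04-09T02:04:49Z,2021-04-09T02:47:11Z,15,18,4
m00029,g1,2021-04-09T03:01:48Z,2021-04-09T03:48:46Z,23,10,2
m00030,g1,2021-04-09T03:58:54Z,2021-04-09T04:34:26Z,15,18,4
m00031,g1,2021-04-09T04:40:46Z,2021-04-09T05:18:30Z,15,18,3
m00032,g1,2021-04-09T18:33:20Z,2021-04-09T19:13:09Z,21,17,4
m00033,g1,2021-04-09T22:05:32Z,2021-04-09T22:48:08Z,14,23,4
m00034,g1,2021-04-09T22:54:48Z,2021-04-09T23:38:01Z,23,14,3
m00035,g1,2021-04-12T01:26:11Z,2021-04-12T02:02:01Z,20,17,4
m00036,g1,2021-04-12T02:08:37Z,2021-04-12T02:59:24Z,25,23,4
m00037,g1,2021-04-12T03:28:24Z,2021-04-12T04:08:04Z,17,9,2
m00038,g1,2021-04-12T04:17:48Z,2021-04-12T05:13:38Z,22,20,7
m00039,g1,2021-04-13T14:02:25Z,2021-04-13T14:46:26Z,14,15,3
m00040,g1,2021-04-13T15:01:09Z,2021-04-13T15:39:22Z,15,19,2
m00041,g1,2021-04-13T15:47:50Z,2021-04-13T16:29:31Z,24,16,7
m00042,g1,2021-04-13T16:44:36Z,2021-04-13T17:29:02Z,16,18,2
m00043,g1,2021-04-13T17:38:42Z,2021-04-13T18:21:10Z,23,21,7
m00044,g1,2021-04-13T18:37:34Z,2021-04-13T19:20:28Z,17,18,4
m00045,g1,2021-04-13T19:40:02Z,2021-04-13T20:11:23Z,24,9,6
m00046,g1,2021-04-13T20:24:36Z,2021-04-13T21:04:55Z,19,22,2
m00047,g1,2021-04-13T21:19:45Z,2021-04-13T21:53:34Z,27,18,2
m00048,g1,2021-04-14T15:49:10Z,2021-04-14T16:33:50Z,19,20,2
m00049,g1,2021-04-14T17:02:36Z,2021-04-14T17:39:53Z,12,16,3
m00050,g1,2021-04-14T17:48:55Z,2021-04-14T18:26:53Z,15,8,6
m00051,g1,2021-04-19T08:39:23Z,2021-04-19T09:16:50Z,24,17,6
m00052,g1,2021-04-19T09:32:24Z,2021-04-19T10:04:12Z,24,12,1
m00053,g1,2021-04-19T10:10:12Z,2021-04-19T10:55:59Z,15,16,2
m00054,g1,2021-04-19T11:08:43Z,2021-04-19T11:44:45Z,22,20,2
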