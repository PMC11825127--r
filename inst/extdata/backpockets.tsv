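pocket	res_num
BP-I	462
BP-I	463
BP-I	481
BP-I	483
BP-I	529
BP-II	500
BP-II	501
BP-II	504
BP-II	505
BP-II	513
BP-II	574
BP-II	594
BP-III	510
BP-III	511
BP-III	512
BP-III	575
BP-III	595
BP-IV	570
BP-IV	573
BP-IV	574
BP-IV	593
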