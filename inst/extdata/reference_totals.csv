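key,value
alerts_pre,113530
alerts_post,93217
dogs_pre,7191
dogs_post,6684
alert_visits_pre,5382
alert_visits_post,6980
visits_pre,15278
visits_post,12900
medications_pre,10829
medications_post,9863
medications_within_4wk_pre,4201
medications_within_4wk_post,5457
week1_pre,3888
week2_pre,1007
week3_pre,328
week4_pre,159
outside_window_pre,9896
week1_post,3626
week2_post,1690
week3_post,1019
week4_post,645
outside_window_post,5920
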